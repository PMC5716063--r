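region,reporting_unit,reef_zone,area_ha
Northwestern Hawaiian Islands,FFS,Backreef,1136
Northwestern Hawaiian Islands,FFS,Forereef,16902
Northwestern Hawaiian Islands,FFS,Lagoon,9728
Northwestern Hawaiian Islands,Kure,Backreef,313
Northwestern Hawaiian Islands,Kure,Forereef,2438
Northwestern Hawaiian Islands,Kure,Lagoon,948
Northwestern Hawaiian Islands,Laysan,Forereef,3400
Northwestern Hawaiian Islands,Lisianski,Forereef,30955
Northwestern Hawaiian Islands,Midway,Backreef,415
Northwestern Hawaiian Islands,Midway,Forereef,3294
Northwestern Hawaiian Islands,Midway,Lagoon,1287
Northwestern Hawaiian Islands,P&H,Backreef,1471
Northwestern Hawaiian Islands,P&H,Forereef,8498
Northwestern Hawaiian Islands,P&H,Lagoon,7843
main Hawaiian Islands,Hawaii,Forereef,16840
main Hawaiian Islands,Kahoolawe,Forereef,1200
main Hawaiian Islands,Kauai,Forereef,18127
main Hawaiian Islands,Lanai,Forereef,3004
main Hawaiian Islands,Maui,Forereef,11122
main Hawaiian Islands,Molokai,Forereef,12730
main Hawaiian Islands,Niihau,Forereef,9266
main Hawaiian Islands,Oahu,Forereef,25119
Pacific Remote Island Areas,Baker,Forereef,390
Pacific Remote Island Areas,Howland,Forereef,173
Pacific Remote Island Areas,Jarvis,Forereef,366
Pacific Remote Island Areas,Johnston,Backreef,357
Pacific Remote Island Areas,Johnston,Forereef,6574
Pacific Remote Island Areas,Johnston,Lagoon,2913
Pacific Remote Island Areas,Kingman,Backreef,473
Pacific Remote Island Areas,Kingman,Forereef,2298
Pacific Remote Island Areas,Kingman,Lagoon,1090
Pacific Remote Island Areas,Kingman,Other,13
Pacific Remote Island Areas,Palmyra,Backreef,1327
Pacific Remote Island Areas,Palmyra,Forereef,2793
Pacific Remote Island Areas,Palmyra,Lagoon,74
Pacific Remote Island Areas,Palmyra,Other,19
Pacific Remote Island Areas,Wake,Backreef,695
Pacific Remote Island Areas,Wake,Forereef,280
Pacific Remote Island Areas,Wake,Lagoon,307
American Samoa,O&O,Forereef,793
American Samoa,Rose,Backreef,171
American Samoa,Rose,Forereef,120
American Samoa,Rose,Lagoon,104
American Samoa,Rose,Other,46
American Samoa,Swains,Forereef,281
American Samoa,Tau,Forereef,904
American Samoa,Tutuila,Forereef,4182
Northern Marianas,Agrihan,Forereef,851
Northern Marianas,AGS,Forereef,744
Northern Marianas,Asuncion,Forereef,249
Northern Marianas,FDP,Forereef,138
Northern Marianas,Maug,Forereef,314
Northern Marianas,Pagan,Forereef,1513
Northern Marianas,Aguijan,Forereef,406
Southern Marianas,Guam,Forereef,7296
Southern Marianas,Rota,Forereef,1331
Southern Marianas,Saipan,Backreef,598
Southern Marianas,Saipan,Forereef,3539
Southern Marianas,Saipan,Lagoon,583
Southern Marianas,Saipan,Other,127
Southern Marianas,Tinian,Forereef,1414
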