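species,group,n
Melanocorypha calandra,resident,794
Calandrella brachydactyla,resident,262
Galerida cristata,resident,2922
Pycnonotus xanthopygos,resident,415
Turdus merula,resident,3685
Parus ater,resident,890
Parus caeruleus,resident,1479
Parus major,resident,3590
Sitta europaea,resident,388
Sitta tephronota,resident,198
Sitta neumayer,resident,1024
Garrulus glandarius,resident,2407
Pica pica,resident,3904
Corvus monedula,resident,2237
Corvus corone palescens,resident,4234
Corvus corax,resident,936
Passer domesticus,resident,5097
Passer montanus,resident,177
Petronia petronia,resident,533
Carduelis carduelis,resident,3275
Hirundo daurica,migratory,700
Erythropygia galactotes,migratory,669
Hippolais olivetorum,migratory,65
Sylvia cantillans,migratory,35
Phylloscopus trochiloides,migratory,25
Phylloscopus sindianus,migratory,29
Lanius nubicus,migratory,411
Carpodacus erythrinus,migratory,260
Emberiza caesia,migratory,141
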