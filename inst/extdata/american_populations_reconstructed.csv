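population,region,language_family,latitude,longitude
Chipewyan,Canada,Na-Dene,59.6,-107.3
Cree,Canada,Algic,50.3,-102.5
Ojibwa,Canada,Algic,46.5,-81.2
Pima,Northern Mexico,Uto-Aztecan,29.0,-108.0
Huichol,Mesoamerica,Uto-Aztecan,22.0,-104.0
Maya,Mesoamerica,Mayan,20.7,-89.0
Mixe,Mesoamerica,Mixe-Zoque,17.0,-96.0
Mixtec,Mesoamerica,Oto-Manguean,17.1,-97.3
Zapotec,Mesoamerica,Oto-Manguean,16.5,-96.5
Cabecar,Costa Rica-Panama,Chibchan,9.5,-84.0
Guaymi,Costa Rica-Panama,Chibchan,8.5,-81.5
Arhuaco,Coastal Colombia,Chibchan,10.9,-73.8
Kogi,Coastal Colombia,Chibchan,11.0,-74.0
Embera,Coastal Colombia,Chocoan,7.0,-76.5
Waunana,Coastal Colombia,Chocoan,5.0,-77.0
Wayuu,Coastal Colombia,Arawakan,11.5,-72.5
Zenu,Coastal Colombia,Zenu,9.0,-75.5
Inga,Inland Colombia,Quechuan,1.0,-77.0
Piapoco,Inland Colombia,Arawakan,3.0,-68.0
Quechua,Andes,Quechuan,-14.0,-74.0
Aymara,Andes,Aymaran,-16.5,-68.0
Huilliche,Andes,Araucanian,-41.0,-73.0
Karitiana,Amazonia and Paraguay,Tupi-Guarani,-9.3,-63.3
Surui,Amazonia and Paraguay,Tupi-Guarani,-11.0,-62.0
Ticuna Arara,Amazonia and Paraguay,Ticuna-Yuri,-4.0,-70.0
Ticuna Tarapaca,Amazonia and Paraguay,Ticuna-Yuri,-4.2,-69.7
Ache,Amazonia and Paraguay,Tupi-Guarani,-25.0,-55.5
Guarani,Southern Brazil,Tupi-Guarani,-23.0,-54.0
Kaingang,Southern Brazil,Je,-27.0,-52.5
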