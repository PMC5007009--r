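# Waypoint route library for distances from a Beringia-analog origin.
# Routes encode the qualitative dispersal-path descriptions used in
# admixture-aware cline analyses of the Americas: north-coast paths for the
# Canadian populations, a Pacific-coast corridor for Mesoamerica and the
# Andes, a detour through Mesoamerica for the Pima (farming/language
# dispersal hypothesis), Amazon-river paths for the Brazilian isolates, and
# a South Atlantic coastal path for the Ache. Waypoint coordinates are
# editable approximations; populations not listed fall back to the direct
# great-circle distance from the origin.
origin: [66.0, -167.0]
routes:
  Chipewyan:
    - [70.0, -140.0]
    - [68.5, -115.0]
  Cree:
    - [70.0, -140.0]
    - [68.5, -110.0]
    - [60.0, -95.0]
  Ojibwa:
    - [70.0, -140.0]
    - [68.5, -110.0]
    - [58.0, -94.0]
  Pima:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [23.0, -106.0]
    - [19.0, -103.0]
  Huichol:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [23.0, -106.0]
  Maya:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [19.0, -103.0]
  Mixe:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
  Mixtec:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
  Zapotec:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
  Quechua:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
    - [8.0, -79.5]
    - [-5.0, -81.0]
  Aymara:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
    - [8.0, -79.5]
    - [-5.0, -81.0]
    - [-17.0, -72.0]
  Huilliche:
    - [55.0, -131.0]
    - [40.0, -124.0]
    - [16.5, -99.0]
    - [8.0, -79.5]
    - [-5.0, -81.0]
    - [-18.0, -70.5]
    - [-33.0, -71.6]
  Karitiana:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-3.1, -60.0]
  Surui:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-3.1, -60.0]
  Ticuna Arara:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-3.1, -60.0]
  Ticuna Tarapaca:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-3.1, -60.0]
  Ache:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-23.0, -43.0]
    - [-34.6, -58.4]
  Guarani:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-23.0, -43.0]
  Kaingang:
    - [55.0, -131.0]
    - [30.0, -115.0]
    - [9.0, -79.5]
    - [0.0, -50.0]
    - [-23.0, -43.0]
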