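name: builtin_bioreactor
members:
- name: Prevotella
  file: Prevotella.csv
  strains: 1
- name: Megasphaera
  file: Megasphaera.csv
  strains: 1
- name: RC9
  file: RC9.csv
  strains: 1
- name: Streptococcus
  file: Streptococcus.csv
  strains: 1
- name: Lactobacillus
  file: Lactobacillus.csv
  strains: 1
- name: Alloprevotella
  file: Alloprevotella.csv
  strains: 1
- name: Clostridium
  file: Clostridium.csv
  strains: 1
- name: Treponema
  file: Treponema.csv
  strains: 1
- name: Faecalibacterium
  file: Faecalibacterium.csv
  strains: 1
- name: Succinivibrio
  file: Succinivibrio.csv
  strains: 1
- name: Blautia
  file: Blautia.csv
  strains: 1
- name: Phascolarctobacterium
  file: Phascolarctobacterium.csv
  strains: 1
- name: Ruminococcus
  file: Ruminococcus.csv
  strains: 1
- name: Parabacteroides
  file: Parabacteroides.csv
  strains: 1
- name: Escherichia
  file: Escherichia.csv
  strains: 1
- name: Turicibacter
  file: Turicibacter.csv
  strains: 1
- name: others
  file: others.csv
  strains: 1
species:
- species: resistant_starch
  role: resource
  molar_mass: 162.14
- species: NSP
  role: resource
  molar_mass: 162.14
- species: protein
  role: resource
  molar_mass: 110.0
- species: sugars
  role: resource
  molar_mass: 180.16
- species: acetate
  role: metabolite
  molar_mass: 60.05
- species: propionate
  role: metabolite
  molar_mass: 74.08
- species: butyrate
  role: metabolite
  molar_mass: 88.11
- species: lactate
  role: metabolite
  molar_mass: 90.08
- species: formate
  role: metabolite
  molar_mass: 46.03
- species: succinate
  role: metabolite
  molar_mass: 118.09
- species: ethanol
  role: metabolite
  molar_mass: 46.07
- species: CO2
  role: metabolite
  molar_mass: 44.01
- species: H2
  role: metabolite
  molar_mass: 2.016
- species: CH4
  role: metabolite
  molar_mass: 16.04
- species: valerate
  role: metabolite
  molar_mass: 102.13
- species: caproate
  role: metabolite
  molar_mass: 116.16
- species: isovalerate
  role: metabolite
  molar_mass: 102.13
initial_abundance:
  Prevotella: 22.2722272
  Megasphaera: 6.6406641
  RC9: 3.820382
  Streptococcus: 5.0805081
  Lactobacillus: 1.950195
  Alloprevotella: 2.330233
  Clostridium: 3.440344
  Treponema: 0.610061
  Faecalibacterium: 0.620062
  Succinivibrio: 0.050005
  Blautia: 0.330033
  Phascolarctobacterium: 0.290029
  Ruminococcus: 0.630063
  Parabacteroides: 0.040004
  Escherichia: 0.010001
  Turicibacter: 0.070007
  others: 51.8151815
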