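name: builtin_cm_only
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
  Prevotella: 46.222499
  Megasphaera: 13.7816521
  RC9: 7.9286011
  Streptococcus: 10.5437941
  Lactobacillus: 4.0473225
  Alloprevotella: 4.8360315
  Clostridium: 7.1398921
  Treponema: 1.2660855
  Faecalibacterium: 1.286841
  Succinivibrio: 0.1037775
  Blautia: 0.6849315
  Phascolarctobacterium: 0.6019095
  Ruminococcus: 1.3075965
  Parabacteroides: 0.083022
  Escherichia: 0.0207555
  Turicibacter: 0.1452885
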