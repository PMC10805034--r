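name: builtin_others_only
members:
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
  others: 100.0
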