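# HEI-2010 component scoring standards.
#
# All standards are densities: amount per 1000 kcal of energy, except
# fatty_acids ((PUFA + MUFA)/SFA, dimensionless) and empty_calories
# (percent of total energy).
#
# density_at_max  earns the full component score; density_at_zero earns 0.
# Adequacy components score linearly upward from 0 density; moderation
# components score linearly downward from density_at_zero; the fatty-acid
# ratio scores linearly upward between its two anchors.
version: "HEI-2010"
components:
  total_fruit:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 0.8
    units: cup-equiv
  whole_fruit:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 0.4
    units: cup-equiv
  total_veg:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 1.1
    units: cup-equiv
  greens_beans:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 0.2
    units: cup-equiv
  whole_grains:
    max_points: 10
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 1.5
    units: oz-equiv
  dairy:
    max_points: 10
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 1.3
    units: cup-equiv
  total_protein:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 2.5
    units: oz-equiv
  seafood_plant_prot:
    max_points: 5
    direction: adequacy
    density_at_zero: 0.0
    density_at_max: 0.8
    units: oz-equiv
  fatty_acids:
    max_points: 10
    direction: ratio
    density_at_zero: 1.2
    density_at_max: 2.5
    units: ratio
  refined_grains:
    max_points: 10
    direction: moderation
    density_at_zero: 4.3
    density_at_max: 1.8
    units: oz-equiv
  sodium:
    max_points: 10
    direction: moderation
    density_at_zero: 2.0
    density_at_max: 1.1
    units: g
  empty_calories:
    max_points: 20
    direction: moderation
    density_at_zero: 50.0
    density_at_max: 19.0
    units: "%energy"
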