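# Rule-based lipid fragmentation templates.
#
# Each class declares a backbone formula; a species formula is
#   backbone + sum(fatty acids) - n_chains * H2O
# (ester or amide linkage both condense one water per chain).
#
# Fragment rule kinds:
#   precursor       - the intact adduct ion
#   ion_formula     - fixed product ion given by its elemental formula
#                     (m/z = monoisotopic mass -/+ electron by polarity)
#   nl_formula      - neutral loss of a fixed formula from the precursor
#   nl_chain_fa     - per acyl chain: neutral loss of the fatty acid
#   nl_chain_ketene - per acyl chain: neutral loss of the acyl ketene (FA - H2O)
#   chain_fa_anion  - per acyl chain: the carboxylate anion RCOO- (negative mode)
#
# retains_adduct: whether the product ion still carries the adduct's charge
# carrier. When a template is borrowed (template: borrow / from:), fragments
# with retains_adduct true are shifted by the difference of the two adduct
# deltas; fragments with retains_adduct false keep their m/z. This encodes
# the working assumption that e.g. [M+NH4]+ fragments like [M+Na]+.
#
# Relative intensities are template values on a 0-100 scale. Fragment mass
# identities follow standard lipidomics fragmentation chemistry (head-group
# ions, acyl neutral losses, carboxylate anions); the intensity values are
# nominal package defaults, not measurements, and are meant to be edited.
# Peaks below 0.2% of the base peak are removed from every generated
# spectrum. A class/adduct block may set mass_only: true to emit uniform
# nominal intensities (for classes whose fragment masses are predictable but
# whose intensities are unknown).

classes:
  PC:
    n_chains: 2
    backbone: C8H20NO6P        # glycerophosphocholine
    adducts:
      "[M+H]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 15, retains_adduct: true}
          - {label: phosphocholine head group, kind: ion_formula, formula: C5H15NO4P,
             intensity: 100, retains_adduct: false}
          - {label: acyl loss as ketene, kind: nl_chain_ketene, intensity: 5,
             retains_adduct: true}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 2,
             retains_adduct: true}
          - {label: water loss, kind: nl_formula, formula: H2O, intensity: 0.1,
             retains_adduct: true}   # below the 0.2% cutoff: never emitted
      "[M+Na]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 100, retains_adduct: true}
          - {label: trimethylamine loss, kind: nl_formula, formula: C3H9N,
             intensity: 80, retains_adduct: true}
          - {label: phosphocholine loss, kind: nl_formula, formula: C5H14NO4P,
             intensity: 40, retains_adduct: true}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 5,
             retains_adduct: true}
      "[M+NH4]+":
        template: borrow
        from: "[M+Na]+"
  PE:
    n_chains: 2
    backbone: C5H14NO6P        # glycerophosphoethanolamine
    adducts:
      "[M+H]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 25, retains_adduct: true}
          - {label: phosphoethanolamine head loss, kind: nl_formula,
             formula: C2H8NO4P, intensity: 100, retains_adduct: true}
          - {label: acyl loss as ketene, kind: nl_chain_ketene, intensity: 5,
             retains_adduct: true}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 2,
             retains_adduct: true}
      "[M-H]-":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 30, retains_adduct: true}
          - {label: fatty acid carboxylate, kind: chain_fa_anion, intensity: 100,
             retains_adduct: false}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 10,
             retains_adduct: true}
          - {label: acyl loss as ketene, kind: nl_chain_ketene, intensity: 15,
             retains_adduct: true}
          - {label: dehydrated glycerophosphoethanolamine, kind: ion_formula,
             formula: C5H11NO5P, intensity: 2, retains_adduct: false}
          - {label: phosphoethanolamine anion, kind: ion_formula,
             formula: C2H7NO4P, intensity: 3, retains_adduct: false}
  PG:
    n_chains: 2
    backbone: C6H15O8P         # glycerophosphoglycerol
    adducts:
      "[M-H]-":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 40, retains_adduct: true}
          - {label: fatty acid carboxylate, kind: chain_fa_anion, intensity: 100,
             retains_adduct: false}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 8,
             retains_adduct: true}
          - {label: acyl loss as ketene, kind: nl_chain_ketene, intensity: 12,
             retains_adduct: true}
          - {label: dehydrated glycerophosphate, kind: ion_formula,
             formula: C3H6O5P, intensity: 5, retains_adduct: false}
          - {label: glycerophosphate anion, kind: ion_formula,
             formula: C3H8O6P, intensity: 3, retains_adduct: false}
      "[M+FA-H]-":
        template: borrow
        from: "[M-H]-"
  TG:
    n_chains: 3
    backbone: C3H8O3           # glycerol
    adducts:
      "[M+Na]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 100, retains_adduct: true}
          - {label: acyl loss as fatty acid, kind: nl_chain_fa, intensity: 30,
             retains_adduct: true}
      "[M+NH4]+":
        template: borrow
        from: "[M+Na]+"
  SM:
    n_chains: 1                # enumerated chain = N-acyl; base fixed d18:1
    backbone: C23H49N2O5P      # sphingosine (d18:1) phosphocholine core
    sphingoid_base: {carbons: 18, double_bonds: 1}
    adducts:
      "[M+H]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 30, retains_adduct: true}
          - {label: phosphocholine head group, kind: ion_formula, formula: C5H15NO4P,
             intensity: 100, retains_adduct: false}
          - {label: water loss, kind: nl_formula, formula: H2O, intensity: 2,
             retains_adduct: true}
      "[M+Na]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 100, retains_adduct: true}
          - {label: trimethylamine loss, kind: nl_formula, formula: C3H9N,
             intensity: 70, retains_adduct: true}
          - {label: phosphocholine loss, kind: nl_formula, formula: C5H14NO4P,
             intensity: 35, retains_adduct: true}
      "[M+NH4]+":
        template: borrow
        from: "[M+Na]+"
  CE:
    n_chains: 1
    backbone: C27H46O          # cholesterol
    adducts:
      "[M+Na]+":
        template: own
        fragments:
          - {label: precursor, kind: precursor, intensity: 30, retains_adduct: true}
          - {label: cholestadienyl cation, kind: ion_formula, formula: C27H45,
             intensity: 100, retains_adduct: false}
      "[M+NH4]+":
        template: borrow
        from: "[M+Na]+"
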