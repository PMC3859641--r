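# Hetero residue codes grouped into the ligand classes used for
# site-to-ligand association. Edit or extend freely; codes are matched
# case-insensitively against HETATM residue names.
energy_currency_electron_carrier:
  - ATP
  - ADP
  - AMP
  - ANP
  - GTP
  - GDP
  - NAD
  - NAP
  - NDP
  - FAD
  - FMN
bivalent_metal:
  - MG
  - ZN
  - CA
  - MN
  - FE
  - FE2
  - NI
  - CU
  - CO
  - CD
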