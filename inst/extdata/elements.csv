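# Per-element constants, version 1 (2026-10).
# Z: atomic number. ionization_energy: first ionization energy in eV,
# rounded to 3 decimals (standard reference values as tabulated by NIST
# and common periodic-table databases).
symbol,Z,ionization_energy
H,1,13.598
C,6,11.260
N,7,14.534
O,8,13.618
F,9,17.423
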