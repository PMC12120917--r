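# Synthetic ReaxFF-style bond-order pair parameters for H/C/N/O/F.
#
# SYNTHETIC DATA: these values are a hand-assembled, representative
# parameter set with the magnitudes and signs typical of published CHON
# ReaxFF parameterizations. They are NOT transcribed from any force-field
# distribution; use them for the uncorrected bond-order image channel,
# not for energetics.
#
# Format: blocks introduced by `pair: <El1> <El2>` followed by key=value
# lines. Radii r0_* in Angstrom; a radius of -1 disables that term
# (sigma / pi / pi-pi respectively). pbo1..pbo6 are the dimensionless
# exponent parameters: BO' = exp[pbo1*(r/r0_sigma)^pbo2]
#                          + exp[pbo3*(r/r0_pi)^pbo4]
#                          + exp[pbo5*(r/r0_pipi)^pbo6].
# Pairs are unordered; one block per pair.

pair: H H
r0_sigma=0.700
r0_pi=-1
r0_pipi=-1
pbo1=-0.079
pbo2=6.059

pair: C H
r0_sigma=1.090
r0_pi=-1
r0_pipi=-1
pbo1=-0.050
pbo2=6.900

pair: C C
r0_sigma=1.380
r0_pi=1.210
r0_pipi=1.180
pbo1=-0.078
pbo2=6.727
pbo3=-0.100
pbo4=9.163
pbo5=-0.455
pbo6=37.610

pair: C N
r0_sigma=1.400
r0_pi=1.250
r0_pipi=1.150
pbo1=-0.088
pbo2=6.946
pbo3=-0.210
pbo4=10.500
pbo5=-0.500
pbo6=35.000

pair: C O
r0_sigma=1.370
r0_pi=1.220
r0_pipi=1.130
pbo1=-0.136
pbo2=6.260
pbo3=-0.246
pbo4=11.100
pbo5=-0.550
pbo6=34.000

pair: C F
r0_sigma=1.350
r0_pi=-1
r0_pipi=-1
pbo1=-0.094
pbo2=7.200

pair: N H
r0_sigma=1.020
r0_pi=-1
r0_pipi=-1
pbo1=-0.062
pbo2=6.700

pair: N N
r0_sigma=1.330
r0_pi=1.230
r0_pipi=1.120
pbo1=-0.094
pbo2=7.300
pbo3=-0.200
pbo4=10.200
pbo5=-0.480
pbo6=33.500

pair: N O
r0_sigma=1.300
r0_pi=1.210
r0_pipi=1.120
pbo1=-0.110
pbo2=6.800
pbo3=-0.230
pbo4=10.800
pbo5=-0.520
pbo6=33.000

pair: O H
r0_sigma=0.970
r0_pi=-1
r0_pipi=-1
pbo1=-0.068
pbo2=6.300

pair: O O
r0_sigma=1.390
r0_pi=1.220
r0_pipi=1.200
pbo1=-0.125
pbo2=5.500
pbo3=-0.300
pbo4=9.000
pbo5=-0.350
pbo6=25.000

# Fluorine pairs other than C-F rarely occur in QM9-like CHONF molecules.
# The loader's default override replaces the radii of O-F, F-N and F-H
# (and, by default, F-F) with the -1 sentinel regardless of what stands
# here; positive values are kept so the override itself is testable.
pair: F H
r0_sigma=0.920
r0_pi=-1
r0_pipi=-1
pbo1=-0.060
pbo2=6.500

pair: N F
r0_sigma=1.360
r0_pi=-1
r0_pipi=-1
pbo1=-0.090
pbo2=7.000

pair: O F
r0_sigma=1.420
r0_pi=-1
r0_pipi=-1
pbo1=-0.095
pbo2=6.900

pair: F F
r0_sigma=1.410
r0_pi=-1
r0_pipi=-1
pbo1=-0.085
pbo2=6.800
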