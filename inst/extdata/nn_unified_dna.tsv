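# Unified oligonucleotide nearest-neighbor parameters for DNA/DNA duplexes
# (SantaLucia 1998 unified set), 1 M NaCl reference state.
# Columns: key <TAB> dH [kcal/mol] <TAB> dS [cal/(mol K)]
# Stack rows are keyed by the 5'->3' top-strand dimer of the quartet; the
# bottom strand is its Watson-Crick complement (e.g. AC == 5'AC3'/3'TG5').
# INIT_STRONG / INIT_WEAK: duplex initiation per terminal base pair with a
#   C-G / A-T terminus, respectively.
# SALT_COEFF: entropy-only sodium correction, dS(Na+) = dS(1M) +
#   SALT_COEFF * n_stacks * ln([Na+]); dH is salt-independent (unified
#   convention). The coefficient is the published unified value 0.368
#   cal/(mol K) per phosphate-pair (= per intact stack).
# DANGLE_AVG, MM_TERM_AVG, MM_INT_AVG: composition-averaged increments used
#   by the defect-vector energy parametrization of duplexes with pairing
#   errors: one DANGLE_AVG per duplex end carrying an overhang (only the
#   first dangling base counts, standard NN convention); one MM_TERM_AVG per
#   consecutive terminal mismatch (whose Watson-Crick stack is removed); one
#   MM_INT_AVG per internal mismatch (whose two flanking stacks are
#   removed). These three rows are averages over the published dangling-end
#   and single-mismatch nearest-neighbor tables, rounded and calibrated so
#   that the averaged parametrization reproduces ensemble melting and
#   defect-class statistics of random-sequence pools; they are the only
#   reconstructed (non-tabulated) quantities in this file.
AA	-7.9	-22.2
AC	-8.4	-22.4
AG	-7.8	-21.0
AT	-7.2	-20.4
CA	-8.5	-22.7
CC	-8.0	-19.9
CG	-10.6	-27.2
CT	-7.8	-21.0
GA	-8.2	-22.2
GC	-9.8	-24.4
GG	-8.0	-19.9
GT	-8.4	-22.4
TA	-7.2	-21.3
TC	-8.2	-22.2
TG	-8.5	-22.7
TT	-7.9	-22.2
INIT_STRONG	0.1	-2.8
INIT_WEAK	2.3	4.1
DANGLE_AVG	-5.9	-17.8
MM_TERM_AVG	-11.9	-41.2
MM_INT_AVG	-2.0	-8.0
SALT_COEFF	0.368	0
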