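# Small demonstration grid: two Hurst exponents, one length, two
# amplitudes, two contaminant families, all three estimators.
H = 0.3,0.8
N = 64
A = 0,1
kinds = awgn,linear_pos
estimators = HK,DFA1,DFA2
n_reps = 5
master_seed = 42
threshold = 0.1
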