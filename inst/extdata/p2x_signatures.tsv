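# Heuristic P2X-channel signature set (synthetic stand-in for a full domain
# database lookup). Each row is one short consensus loosely modelled on
# conserved P2X receptor elements; detect_p2x_domain() scores a sequence by
# the fraction of these patterns it matches. Users with real domain calls
# should prefer the sidecar-TSV override.
name	notation
p2x_sig_gly	Gx3(L/I/V/M/F/Y)x2(L/I/V/M)xGG(L/I/V/M)(L/I/V/M/F)(G/Q)
p2x_sig_fcp	(F/Y)(C/V)Px6(S/A)(L/I/V/M/F)
p2x_sig_dome	(F/Y)G(L/I/V)R(F/Y)D(L/I/V)(L/I/V)
p2x_sig_tm	(L/I/V)(L/I/V)x(S/T)G(L/I/V)(A/G)x2(L/I/V)
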