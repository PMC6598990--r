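# Unregulated self-renewal, regulated division; maturation rate constant in
# both maturity and mature cells (g = g0 + 0.4), so the delay is fixed.
scenario: "(s)_d,(pv)_0,(px)_1"
p: 2
mu: 1
g0: 0
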