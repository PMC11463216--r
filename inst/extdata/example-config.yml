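# Example configuration: a branching colony with a wider branching angle.
# Load with load_config() or run with:
#   exec/coralsim run --config inst/extdata/example-config.yml --out out/
smin: 0.375
smax: 1
nu: 10          # mm/yr
delta_sub: 10   # mm
l_br: 40        # mm (enables branching; epsilon = 0.25 * l_br)
theta: 45       # degrees
t_end: 20       # yr
seed: 1
snapshot_every: 5
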