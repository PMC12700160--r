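# Shared objects, built once per test session. The default community is
# cheap to construct; simulations are run inside the tests that need them.
nf_comm <- community()
nf_traits <- trait_table(nf_comm)
nf_v <- nf_comm$kinetics$v_max
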