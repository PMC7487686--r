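ESR_induced	synthetic example: induced arm of an ESR-like program on the default simulated genome	gIII.001	gIII.002	gIII.003	gIV.001	gIV.002	gIV.003	gV.001	gV.002	gVI.001	gVI.002
ESR_repressed	synthetic example: repressed arm of an ESR-like program	gIII.004	gIII.005	gIV.004	gIV.005	gV.003	gV.004	gVI.003	gVI.004
HSR	synthetic example: heat-shock-like set	gVII.001	gVII.002	gVII.003	gIX.001	gIX.002	gX.001
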