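# Domain annotation for the synthetic hinged tetramer produced by
# generateHingedMultimer(nChains = 4, helixLengths = c(10, 10)).
# Residue indices are the internal 0-based within-chain positions; the chain
# order declares the counter-clockwise subunit cycle viewed from the
# extracellular side.
numbering_offset: 1
chain_order: [A, B, C, D]
insertion_site: [9, 10]
regions:
  S6: {from: 0, to: 9}
  CL: {from: 10, to: 19}
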