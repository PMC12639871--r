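# The twelve confirmed-case diplotypes, transcribed from the study's
# comparison table of traditional biochemical screening and long-read
# results. Variant names are coding-style; structural alleles name the
# chimera class and junction bin. Uncertain-significance and
# likely-pathogenic passengers ride on the haplotype they were reported
# with; one VUS whose printed coding position exceeds any plausible CDS is
# kept in the knowledge base only and is not simulated.
cases:
  - id: case01
    hapA:
      variants: [c.518T>A]
    hapB:
      variants: [c.844G>T, c.923dup, c.955C>T, c.1069C>T]
  - id: case02
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.518T>A]
  - id: case03
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.740del, c.*1316C>T]
  - id: case04
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.518T>A]
  - id: case05
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.518T>A, c.*1215C>T, c.*1316C>T, c.*1351G>C]
  - id: case06
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.293-13C>G]
  - id: case07
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.518T>A]
  - id: case08
    hapA:
      variants: [c.293-13C>G]
    hapB:
      variants: [c.293-13C>G]
  - id: case09
    hapA:
      variants: [c.518T>A]
    hapB:
      variants: [c.518T>A]
  - id: case10
    hapA:
      variants: [c.92C>T]
    hapB:
      variants: [c.92C>T]
  - id: case11
    hapA:
      structure: TNX_CHIMERA
      bin: TNX-CH-1
    hapB:
      structure: DEL_CHIMERA
      bin: CH-8
  - id: case12
    hapA:
      variants: [c.518T>A]
    hapB:
      structure: DEL_CHIMERA
      bin: CH-1
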