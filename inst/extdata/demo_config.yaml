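# Bundled demonstration configuration: a compact synthetic study that
# exercises every pipeline stage in a few seconds.  The synthetic genome is
# 2 Mb (2,000 variants at 1 kb spacing), so the clumping distance is scaled
# down from the genome-scale default accordingly.
seed: 11
simulation:
  nIndividuals: 400
  nVariants: 2000
  blockSize: 25
  gwasN: 50000
  nPeaks: 800
  nCellStates: 4
  peakWidth: 500
  nLeads: 20
  specificityFraction: 0.1
plantedTau:
  active: 5.0e-5
windowBp: 50000
clump:
  distanceBp: 20000
pathways:
  nGenes: 100
  geneWidth: 5000
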