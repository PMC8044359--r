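# Compact end-to-end pipeline configuration: two small panels, two
# endophenotypes plus the focal trait, two marker-effect methods, short
# chains. Used for quick smoke runs; outDir and seed are normally
# overridden on the command line or by the caller.
preset: test
seed: 1
sim:
  nLinesDiscovery: 100
  nLinesElite: 80
  nOverlap: 8
  nMarkers: 400
  nLdBlocks: 80
  nFoundersPerBlock: 6
  mafMin: 0.02
  driftSd: 1
  residualHetRate: 0.005
traits:
  endophenotypes:
    - traitId: E1
      nQtl: 15
      effectDistribution: scaled_t
      h2: 0.7
    - traitId: E2
      nQtl: 150
      effectDistribution: gaussian
      h2: 0.45
  focal:
    weights: [0.6, 0.4]
    extraPolygenicShare: 0.2
    h2: 0.4
design:
  nBlocks: 8
  nChecks: 2
  batchSize: 20
  blockVarShare: 0.1
  batchVarShare: 0.05
  trialVarShare: 0.05
  covariateBeta: 0.3
  nTrialsElite: 2
methods: [BRR, BayesB]
cv:
  k: 5
  nRuns: 3
  threshold: 0.9
  reliabilityFloor: 0.1
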