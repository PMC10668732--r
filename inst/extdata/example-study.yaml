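# Example merinosim study configuration.
# Everything is optional; omitted keys fall back to the package defaults.
study:
  profile: desk          # desk = scale 0.1, 10 replicates; full = 1.0, 50
  n_cycles: 20
  reference_cycle: 10
  seed: 1
  n_qtl: 1000
  burn_in_generations: 5
  st_progeny_per_sire: 8
  ft_progeny_per_sire: 20
  na_fraction: 0.25
  ft_disjoint: false
program:
  scale_factor: 0.1      # cohort sizes (below) are full scale; this scales them
  n_breeding_rams: 469
  n_breeding_ewes: 7185
  litter_probs: [0.56, 0.40, 0.04]
  lamb_mortality: 0.1
  male_selected_fraction: 0.02
  female_selected_fraction: 0.20
  licensing_rejection_fraction: 0.1
correlations:
  gxe: 0.8               # field-station genetic correlation (G x E)
genome:
  n_chromosomes: 26
  loci_per_chromosome: 200
  map_length: 1.0
traits:
  h2:
    NL: 0.10             # override heritabilities by trait name
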