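# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# evolve a sequence under the generator's K2P process (internal helper)
evolve <- function(seq, k) mitescout:::evolve_seq(seq, k)

# a small planted-family simulation reused across modules:
# 100 kb, one 670 bp family with 14 bp TIRs and 8 bp TSDs, 10 copies,
# half of them undiverged and half at ~2 Myr
small_sim <- function() {
  get_fixture("small_sim", function() {
    cfg <- mite_config()
    sim <- simulate_genome(100000, gc = 0.4, n_genes = 8, seed = 101)
    sp <- mite_plant_spec("famA", length = 670, tir_len = 14, tsd_len = 8,
                          n_copies = 10, at_fraction = 0.70,
                          ages = tibble::tibble(T_years = c(0, 2e6),
                                                weight = c(0.5, 0.5)))
    sim <- plant_mites(sim, sp, cfg, seed = 102)
    list(sim = sim, spec = sp, cfg = cfg)
  })
}

# an MSA of 12 substitution-only descendants of one ancestor (no indels,
# so rows are already aligned), ancestor included as attribute
family_msa <- function(k = 0.05, n = 12, len = 400, seed = 7) {
  set.seed(seed)
  anc <- random_dna(len, gc = 0.35)
  rows <- vapply(seq_len(n), function(i) evolve(anc, k), "")
  msa <- tibble::tibble(taxon = sprintf("m%02d", seq_len(n)), aligned = rows)
  attr(msa, "ancestor") <- anc
  msa
}
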