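# Shared fixtures, built once per test run.  Everything is generated in
# code; no data files.

.fix <- new.env()

small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_genes = 600, n_wgd = 40, n_ssd = 25, seed = seed, ...)
}

fixture_genes <- function() {
  if (is.null(.fix$genes)) .fix$genes <- generate_gene_table(small_spec())
  .fix$genes
}

fixture_pairs <- function() {
  if (is.null(.fix$pairs))
    .fix$pairs <- generate_paralog_pairs(small_spec(), fixture_genes())
  .fix$pairs
}

fixture_records <- function() {
  if (is.null(.fix$records)) {
    pp <- fixture_pairs()
    .fix$records <- divergence_records(pp$genes, pp$pairs)
  }
  .fix$records
}

# a modest rate pool for evolution tests
fixture_pool <- function() fixture_genes()
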