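# Shared fixtures built in code.

# single exponential population growing from t = 0, used for self-consistency
single_pop_config <- function(n0 = 500, td = 2, cs = 10, noise_cv = 0,
                              seed = 1L) {
  simulation_config(
    populations = list(population_spec(
      "solo", n0 = n0, doubling_time_h = td, onset_h = 0, cs_srr = cs,
      substrates = c(lactate = 2), products = c(acetate = 2))),
    time_grid = seq(0, 24, by = 2),
    sulfate_init = 20, vfa_init = c(lactate = 50, acetate = 0),
    noise_cv = noise_cv, seed = seed
  )
}

# tiny asv_table: counts matrix + minimal metadata; tree optional
tiny_asv_table <- function(counts, timepoints = NULL, treatments = NULL,
                           tree = NULL, lineages = NULL) {
  libs <- colnames(counts)
  meta <- tibble::tibble(
    library_id = libs,
    treatment = treatments %||% rep("amended", length(libs)),
    timepoint_h = timepoints %||% seq_along(libs)
  )
  tax <- tibble::tibble(
    asv_id = rownames(counts),
    lineage = lineages %||% rep("Bacteria;Bacillota;Clostridia;;;",
                                nrow(counts))
  )
  asv_table(counts, meta, tax, tree)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force weighted UniFrac: enumerate each branch's descendant tips by
# recursive edge walking, independent of the package's postorder traversal
brute_unifrac <- function(tree, p, q, normalized = TRUE) {
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    A <- sum(p[tips])
    B <- sum(q[tips])
    num <- num + tree$edge.length[e] * abs(A - B)
    den <- den + tree$edge.length[e] * (A + B)
  }
  if (!normalized) num else if (den == 0) 0 else num / den
}
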