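# Shared fixtures (memoised: alignment-based numbering is the slow part) and
# independent oracles used across test files.

.fx <- new.env(parent = emptyenv())

fx <- function(name, make) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(make)
  .fx[[name]]
}

fx_refs <- function() fx("refs", reference_sequences())

fx_heavy_numbered <- function()
  fx("hnum", number_chain(chain_sequence("ref_vh", "heavy", fx_refs()[["heavy"]])))

fx_kappa_numbered <- function()
  fx("knum", number_chain(chain_sequence("ref_vk", "light", fx_refs()[["kappa"]])))

# heavy reference with its template CDR-H3 ("DGGYSGDY") replaced
heavy_with_loop <- function(loop)
  sub("DGGYSGDY", loop, fx_refs()[["heavy"]], fixed = TRUE)

fx_repertoire <- function()
  fx("rep30", generate_repertoire(repertoire_spec(30, seed = 7)))

# ray-casting point-in-polygon: the independent containment oracle
in_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# dense kernel-PCA oracle: explicit centering matrix + eigen()
kpca_oracle <- function(X, gamma, ncomp = 2) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(stats::dist(X))^2)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  eig <- eigen(Kc, symmetric = TRUE)
  sweep(eig$vectors[, seq_len(ncomp), drop = FALSE], 2,
        sqrt(eig$values[seq_len(ncomp)]), "*")
}

# compare projections up to per-component sign
expect_proj_equal <- function(a, b, tol = 1e-8) {
  for (j in seq_len(ncol(a))) {
    d <- min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
    expect_lt(d, tol)
  }
}

# charge curve oracle: vectorised Henderson-Hasselbalch directly off the
# packaged pKa CSV (independent of net_charge / isoelectric_point)
charge_curve <- function(seq, ph) {
  tab <- read.csv(system.file("extdata", "pka_emboss.csv", package = "abtriage"),
                  comment.char = "#")
  ch <- strsplit(seq, "")[[1]]
  q <- numeric(length(ph))
  for (i in seq_len(nrow(tab))) {
    g <- tab$group[i]
    n <- if (g %in% c("Nterm", "Cterm")) 1 else sum(ch == g)
    if (n == 0) next
    q <- q + if (tab$sign[i] == "positive") n / (1 + 10^(ph - tab$pka[i]))
             else -n / (1 + 10^(tab$pka[i] - ph))
  }
  q
}

random_peptide <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

# small reference sets for pipeline tests (generated once)
fx_pipeline_sets <- function() fx("pipe", list(
  clinical = generate_repertoire(
    repertoire_spec(10, mutation_rate = 0.01, cdrh3_sd = 2, seed = 11),
    status = "clinical", prefix = "cln"),
  library = generate_repertoire(repertoire_spec(25, seed = 12),
                                status = "library", prefix = "lib"),
  approved = generate_repertoire(
    repertoire_spec(8, mutation_rate = 0.01, cdrh3_sd = 2, seed = 13),
    status = "approved", prefix = "app"),
  discontinued = generate_repertoire(
    repertoire_spec(8, mutation_rate = 0.05, seed = 14),
    status = "discontinued", prefix = "dis"),
  query = generate_repertoire(repertoire_spec(16, seed = 15),
                              status = "query", prefix = "qry")))
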