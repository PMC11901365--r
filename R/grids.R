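#' Canonical Chothia position grids
#'
#' The pipeline aligns every variable domain onto a fixed list of Chothia
#' position labels: 132 slots for the heavy chain (H1..H113 plus insertion
#' slots H31A-B, H52A-C, H82A-C, H100A-K) and 122 for the light chain
#' (L1..L107 plus L30A-G, L95A-G, L106A). The slot lists are shipped as plain
#' text under `inst/extdata` together with a full-grid consensus residue per
#' slot (used by the alignment-based numbering backend) and a `core` flag
#' marking the slots occupied by the packaged germline references.
#'
#' @param chain_type `"heavy"` or `"light"`.
#' @param pad_char single padding character (encoder-specific; `"_"` default).
#' @return A `grid_spec`: list with `chain_type`, `labels`, `slot_count`,
#'   `pad_char`.
#' @examples
#' g <- grid_spec("heavy")
#' g$slot_count  # 132
#' @export
grid_spec <- function(chain_type = c("heavy", "light"), pad_char = "_") {
  chain_type <- match.arg(chain_type)
  stopifnot(is.character(pad_char), nchar(pad_char) == 1L)
  tab <- grid_table(chain_type)
  expected <- if (chain_type == "heavy") 132L else 122L
  if (nrow(tab) != expected)
    ab_stop("ab_parse_error", sprintf(
      "packaged %s grid has %d slots, expected %d", chain_type, nrow(tab), expected))
  structure(list(chain_type = chain_type, labels = tab$label,
                 slot_count = nrow(tab), pad_char = pad_char),
            class = "grid_spec")
}

# cached packaged tables -------------------------------------------------

.ab_cache <- new.env(parent = emptyenv())

grid_table <- function(chain_type) {
  key <- paste0("grid_", chain_type)
  if (!is.null(.ab_cache[[key]])) return(.ab_cache[[key]])
  f <- system.file("extdata",
                   sprintf("chothia_%s_grid.tsv", chain_type),
                   package = "abtriage", mustWork = TRUE)
  tab <- utils::read.delim(f, colClasses = "character")
  for (nm in grep("core$", names(tab), value = TRUE)) tab[[nm]] <- as.integer(tab[[nm]])
  .ab_cache[[key]] <- tab
  tab
}

# Full-grid consensus string for the alignment backend (one residue per slot).
grid_consensus <- function(chain_type, which = c("consensus", "kappa", "lambda")) {
  which <- match.arg(which)
  tab <- grid_table(chain_type)
  paste(tab[[which]], collapse = "")
}

#' Packaged germline-like reference sequences
#'
#' Returns the residues of the packaged consensus references restricted to
#' their occupied (`core`) grid slots: a heavy VH3-family-like domain with an
#' 8-residue CDR-H3, and kappa/lambda light-chain V-J references. These anchor
#' the numbering backend, the kappa/lambda typer and the synthetic repertoire
#' templates.
#'
#' @return Named character vector with elements `heavy`, `kappa`, `lambda`.
#' @export
reference_sequences <- function() {
  h <- grid_table("heavy"); l <- grid_table("light")
  c(heavy  = paste(h$consensus[h$core == 1L], collapse = ""),
    kappa  = paste(l$kappa[l$kappa_core == 1L], collapse = ""),
    lambda = paste(l$lambda[l$lambda_core == 1L], collapse = ""))
}
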