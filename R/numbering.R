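#' Construct a validated chain sequence
#'
#' @param id record identifier.
#' @param chain_type `"heavy"` or `"light"`.
#' @param residues one-letter amino-acid string (uppercase, 20 standard codes).
#' @return A `chain_sequence` object.
#' @export
chain_sequence <- function(id, chain_type = c("heavy", "light"), residues) {
  chain_type <- match.arg(chain_type)
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues))
    ab_stop("ab_invalid_alphabet", sprintf("%s: empty sequence", id))
  bad <- setdiff(strsplit(residues, "")[[1]], AA20)
  if (length(bad))
    ab_stop("ab_invalid_alphabet", sprintf(
      "%s: non-standard residue code(s): %s", id, paste(unique(bad), collapse = ", ")))
  structure(list(id = as.character(id), chain_type = chain_type,
                 residues = residues), class = "chain_sequence")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @export
print.chain_sequence <- function(x, ...) {
  cat(sprintf("<chain_sequence> %s (%s, %d aa)\n", x$id, x$chain_type,
              nchar(x$residues)))
  invisible(x)
}

# Alignment backend -------------------------------------------------------

blosum62 <- function() {
  if (is.null(.ab_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ab_cache$blosum62 <- e$BLOSUM62
  }
  .ab_cache$blosum62
}

align_to_consensus <- function(residues, consensus) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(residues),
    subject = Biostrings::AAString(consensus),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 25, gapExtension = 1)
}

# Walk an alignment and transfer grid slot labels to the query residues.
# A query residue aligned against a consensus gap gets label NA plus the slot
# index it was inserted after; the CDR repacking step decides whether such
# residues can legally sit on a sanctioned insertion slot.
transfer_labels <- function(aln, labels) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  slot <- 0L
  out <- data.frame(slot = integer(0), after = integer(0),
                    residue = character(0))
  for (i in seq_along(s)) {
    if (s[i] != "-") slot <- slot + 1L
    if (p[i] == "-") next
    out[nrow(out) + 1L, ] <- list(
      if (s[i] == "-") NA_integer_ else slot, slot, p[i])
  }
  out
}

# Canonicalise each CDR window: pool the residues assigned inside the window
# together with any aligner "insertions" adjacent to it, then repack them in
# sequence order onto the window's slots -- base slots before the insertion
# block first, the slots after the block filled from the loop's far end, and
# the sanctioned insertion letters (H100A.., L30A.., ...) taking the middle
# overflow. This reproduces the numbering convention (e.g. a 14-residue
# lambda CDR-L1 occupies L24-L30, L30A-C, L31-L34) and makes loop lengths
# independent of where the aligner opened gaps inside hypervariable windows.
repack_windows <- function(tab, chain_type, labels, id) {
  loops <- if (chain_type == "heavy") c("H1", "H2", "H3") else c("L1", "L2", "L3")
  for (lp in loops) {
    win <- cdr_window_labels(chain_type, lp, labels)
    wi <- match(win, labels)
    pool <- which((!is.na(tab$slot) & tab$slot %in% wi) |
                  (is.na(tab$slot) & tab$after >= min(wi) - 1L &
                     tab$after <= max(wi)))
    if (!length(pool)) next
    n <- length(pool)
    if (n > length(win))
      ab_stop("ab_grid_overflow", sprintf(
        "%s: %d residues in %s window exceed its %d canonical slots",
        id, n, lp, length(win)))
    base <- !grepl("[A-Z]$", sub("^[HL]", "", win))
    ins_at <- which(!base)
    suffix <- if (length(ins_at)) which(base & seq_along(win) > max(ins_at))
              else integer(0)
    prefix <- setdiff(which(base), suffix)
    tail_n <- min(length(suffix), n)
    head_slots <- c(prefix, ins_at)[seq_len(n - tail_n)]
    if (n - tail_n > length(prefix) + length(ins_at))
      ab_stop("ab_grid_overflow", sprintf(
        "%s: cannot place %d residues in %s window", id, n, lp))
    slots <- wi[c(head_slots, utils::tail(suffix, tail_n))]
    tab$slot[pool] <- slots  # pool is in query order, slots in grid order
  }
  if (anyNA(tab$slot))
    ab_stop("ab_grid_overflow", sprintf(
      "%s: insertion outside scheme-sanctioned positions", id))
  tab[order(tab$slot), , drop = FALSE]
}

#' Number a variable-domain sequence on the Chothia grid
#'
#' Aligns the query against a packaged full-grid consensus (heavy; or the
#' better-scoring of the kappa/lambda consensi for light chains) and transfers
#' the canonical slot labels. Residues that cannot be placed on the 132/122
#' grid raise a grid-overflow error; sequences whose conserved cysteine
#' anchors (H22/H92, L23/L88) are absent are rejected as unnumberable.
#'
#' @param chain a [chain_sequence()].
#' @return A `numbered_chain`: list with `chain_type`, `id`, `labels`
#'   (e.g. `"H100A"`), `residues` (one character each), and for light chains
#'   the `consensus_used` (`"kappa"`/`"lambda"`).
#' @examples
#' refs <- reference_sequences()
#' nc <- number_chain(chain_sequence("vh", "heavy", refs[["heavy"]]))
#' head(nc$labels)
#' @export
number_chain <- function(chain) {
  stopifnot(inherits(chain, "chain_sequence"))
  n <- nchar(chain$residues)
  if (n < 70L || n > 150L)
    ab_stop("ab_unnumberable", sprintf(
      "%s: length %d outside numberable range [70, 150]", chain$id, n))
  labels <- grid_table(chain$chain_type)$label
  if (chain$chain_type == "heavy") {
    aln <- align_to_consensus(chain$residues, grid_consensus("heavy"))
    used <- NULL
    anchors <- c("H22", "H92")
  } else {
    alns <- lapply(c(kappa = "kappa", lambda = "lambda"), function(w)
      align_to_consensus(chain$residues, grid_consensus("light", w)))
    sc <- vapply(alns, Biostrings::score, numeric(1))
    used <- names(which.max(sc))
    aln <- alns[[used]]
    anchors <- c("L23", "L88")
  }
  tab <- repack_windows(transfer_labels(aln, labels), chain$chain_type,
                        labels, chain$id)
  tl <- list(labels = labels[tab$slot], residues = tab$residue)
  got <- tl$residues[match(anchors, tl$labels)]
  if (anyNA(got) || any(got != "C"))
    ab_stop("ab_unnumberable", sprintf(
      "%s: conserved cysteine anchor(s) %s not found",
      chain$id, paste(anchors[is.na(got) | got != "C"], collapse = ", ")))
  structure(list(chain_type = chain$chain_type, id = chain$id,
                 labels = tl$labels, residues = tl$residues,
                 consensus_used = used),
            class = "numbered_chain")
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("<numbered_chain> %s (%s): %d residues, %s..%s\n", x$id,
              x$chain_type, length(x$labels), x$labels[1],
              x$labels[length(x$labels)]))
  invisible(x)
}

#' Concatenated residues of a numbered chain (round-trip accessor)
#' @param numbered a `numbered_chain`.
#' @return single string; equals the original input sequence.
#' @export
chain_residues <- function(numbered) paste(numbered$residues, collapse = "")

#' Pad a numbered chain onto a fixed grid
#'
#' @param numbered a `numbered_chain` (may be empty).
#' @param grid a [grid_spec()] of the same chain type.
#' @return String of exactly `grid$slot_count` characters; slots without an
#'   assigned residue hold `grid$pad_char`.
#' @export
pad_to_grid <- function(numbered, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  out <- rep(grid$pad_char, grid$slot_count)
  if (length(numbered$labels)) {
    idx <- match(numbered$labels, grid$labels)
    if (anyNA(idx))
      ab_stop("ab_grid_overflow", sprintf(
        "%s: label(s) outside the canonical grid: %s", numbered$id,
        paste(numbered$labels[is.na(idx)], collapse = ", ")))
    out[idx] <- numbered$residues
  }
  paste(out, collapse = "")
}

#' Pad a numbered heavy/light pair for a given encoder pad character
#'
#' @param heavy,light `numbered_chain`s.
#' @param pad_char padding character (see [encoder_registry()] specs).
#' @return A `padded_chain_pair`: `heavy_padded` (132 chars), `light_padded`
#'   (122 chars), `id`, `pad_char`.
#' @export
pad_pair <- function(heavy, light, pad_char = "_") {
  hp <- pad_to_grid(heavy, grid_spec("heavy", pad_char))
  lp <- pad_to_grid(light, grid_spec("light", pad_char))
  structure(list(heavy_padded = hp, light_padded = lp,
                 id = heavy$id, pad_char = pad_char),
            class = "padded_chain_pair")
}

# CDR definitions ---------------------------------------------------------

#' CDR window definitions on Chothia-numbered positions
#'
#' Start/end labels (inclusive, insertions included) for each loop under the
#' Kabat, Chothia, or combined Kabat/Chothia ("Martin") definitions. CDR-H3 is
#' fixed at H95-H102 in all three.
#'
#' @param name one of `"kabat"`, `"chothia"`, `"kabat_chothia_martin"`.
#' @return A `cdr_definition`: named list of `c(start, end)` label pairs.
#' @export
cdr_definition <- function(name = c("kabat", "chothia", "kabat_chothia_martin")) {
  name <- match.arg(name)
  w <- switch(name,
    kabat = list(H1 = c("H31", "H35"), H2 = c("H50", "H65"),
                 L1 = c("L24", "L34"), L2 = c("L50", "L56")),
    chothia = list(H1 = c("H26", "H32"), H2 = c("H52", "H56"),
                   L1 = c("L24", "L34"), L2 = c("L50", "L56")),
    kabat_chothia_martin = list(H1 = c("H26", "H35"), H2 = c("H50", "H58"),
                                L1 = c("L24", "L34"), L2 = c("L50", "L56")))
  w$H3 <- c("H95", "H102")
  w$L3 <- c("L89", "L97")
  structure(list(name = name, windows = w), class = "cdr_definition")
}

cdr_window_labels <- function(chain_type, loop, grid_labels = NULL,
                              cdr = cdr_definition()) {
  if (is.null(grid_labels)) grid_labels <- grid_table(chain_type)$label
  win <- cdr$windows[[loop]]
  i <- match(win, grid_labels)
  stopifnot(!anyNA(i), i[1] <= i[2])
  grid_labels[i[1]:i[2]]
}

#' Extract a CDR loop from a numbered chain
#'
#' @param numbered a `numbered_chain`.
#' @param cdr a [cdr_definition()].
#' @param loop `"H1"`, `"H2"`, `"H3"`, `"L1"`, `"L2"` or `"L3"`.
#' @return Loop subsequence (string), insertions included, in grid order.
#' @export
extract_cdr <- function(numbered, cdr = cdr_definition(), loop = "H3") {
  stopifnot(inherits(numbered, "numbered_chain"), inherits(cdr, "cdr_definition"))
  want <- if (startsWith(loop, "H")) "heavy" else "light"
  if (numbered$chain_type != want)
    ab_stop("ab_missing_region", sprintf(
      "%s: loop %s requested from a %s chain", numbered$id, loop,
      numbered$chain_type))
  win <- cdr_window_labels(numbered$chain_type, loop, cdr = cdr)
  hit <- numbered$labels %in% win
  if (!any(hit))
    ab_stop("ab_missing_region", sprintf("%s: no residues in %s window",
                                         numbered$id, loop))
  paste(numbered$residues[hit], collapse = "")
}

# Light-chain typing ------------------------------------------------------

numbered_reference <- function(which) {
  key <- paste0("numref_", which)
  if (is.null(.ab_cache[[key]])) {
    refs <- reference_sequences()
    ct <- if (which == "heavy") "heavy" else "light"
    .ab_cache[[key]] <- number_chain(chain_sequence(which, ct, refs[[which]]))
  }
  .ab_cache[[key]]
}

#' Classify a light chain as kappa or lambda
#'
#' Framework-only ungapped identity (CDR slots are hypervariable and excluded)
#' against the packaged kappa and lambda references; ties resolve to kappa.
#'
#' @param light a light [chain_sequence()] or `numbered_chain`.
#' @return `"kappa"` or `"lambda"`.
#' @export
classify_light_chain <- function(light) {
  nc <- if (inherits(light, "numbered_chain")) light else number_chain(light)
  stopifnot(nc$chain_type == "light")
  cdr_lab <- unlist(lapply(c("L1", "L2", "L3"),
                           function(lp) cdr_window_labels("light", lp)))
  fw_identity <- function(ref) {
    keep <- !(nc$labels %in% cdr_lab)
    i <- match(nc$labels[keep], ref$labels)
    ok <- !is.na(i)
    if (!any(ok)) return(0)
    mean(nc$residues[keep][ok] == ref$residues[i[ok]])
  }
  idk <- fw_identity(numbered_reference("kappa"))
  idl <- fw_identity(numbered_reference("lambda"))
  if (idk >= idl) "kappa" else "lambda"
}
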