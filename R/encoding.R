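# Per-residue encoders turn a padded heavy/light pair into one fixed-length
# numeric vector: heavy grid then light grid, position-major (all embedding
# channels of slot 1, then slot 2, ...). Real language-model adapters are
# registry stubs (their weights cannot ship); the seeded mock encoder gives
# the same contract with zero dependencies.

#' Encoder specification
#'
#' @param name encoder name.
#' @param dim per-residue embedding dimension (position-wise encoders).
#' @param pad_char padding character the encoder expects.
#' @param total_features declared total feature count for a heavy+light pair;
#'   defaults to `(132 + 122) * dim` for position-wise encoders.
#' @param available whether an encoding function is actually present.
#' @return An `encoder_spec`.
#' @export
encoder_spec <- function(name, dim, pad_char,
                         total_features = (132L + 122L) * as.integer(dim),
                         available = FALSE) {
  stopifnot(dim >= 1, nchar(pad_char) == 1L)
  structure(list(name = name, dim = as.integer(dim), pad_char = pad_char,
                 total_features = as.integer(total_features),
                 available = available),
            class = "encoder_spec")
}

#' Deterministic mock encoder
#'
#' Draws one frozen embedding vector per (grid slot, residue) from a seeded
#' generator; pad slots map to the zero vector. The same `(dim, seed)` always
#' yields the same encoder, across sessions.
#'
#' @param dim embedding dimension per residue (default 8).
#' @param seed integer seed.
#' @return An `encoder` object: the [encoder_spec()] plus an `encode`
#'   function taking a `padded_chain_pair`.
#' @export
mock_encoder <- function(dim = 8L, seed = 42L) {
  spec <- encoder_spec("mock", dim, "_", available = TRUE)
  n_slots <- 132L + 122L
  tab <- with_seed(seed, array(stats::rnorm(dim * 20L * n_slots),
                               dim = c(dim, 20L, n_slots)))
  encode <- function(pair) {
    chars <- strsplit(paste0(pair$heavy_padded, pair$light_padded), "")[[1]]
    aa_idx <- match(chars, AA20)          # NA for pad slots
    out <- numeric(dim * n_slots)
    for (s in which(!is.na(aa_idx)))
      out[((s - 1L) * dim + 1L):(s * dim)] <- tab[, aa_idx[s], s]
    out
  }
  structure(list(spec = spec, encode = encode, seed = as.integer(seed)),
            class = "encoder")
}

#' Encoder registry
#'
#' The mock encoder is always available. The published language-model
#' adapters are declared with their measured feature totals and padding
#' characters but have no local weights; requesting one raises an
#' adapter-unavailable error.
#'
#' @return named list of `encoder_spec`s.
#' @export
encoder_registry <- function() {
  list(
    mock      = mock_encoder()$spec,
    antiberty = encoder_spec("antiberty", 512L, "_", 130048L),
    ablang    = encoder_spec("ablang", 768L, "*", 195072L),
    sapiens   = encoder_spec("sapiens", 128L, "*", 152560L),
    esm       = encoder_spec("esm", 320L, "X", 82560L)
  )
}

#' Resolve an encoder by name
#' @param name registry name; only `"mock"` has a local implementation.
#' @param ... passed to [mock_encoder()].
#' @return an `encoder`.
#' @export
get_encoder <- function(name = "mock", ...) {
  reg <- encoder_registry()
  if (!name %in% names(reg))
    ab_stop("ab_adapter_unavailable", sprintf("unknown encoder '%s'", name))
  if (name != "mock")
    ab_stop("ab_adapter_unavailable", sprintf(
      "encoder '%s' requires an external adapter that is not installed", name))
  mock_encoder(...)
}

#' Encode a padded heavy/light pair
#'
#' @param pair a `padded_chain_pair` padded with the encoder's pad character.
#' @param encoder an `encoder` (see [mock_encoder()], [get_encoder()]).
#' @return numeric feature vector of length `encoder$spec$total_features`,
#'   with attributes `id` and `encoder`.
#' @export
encode_pair <- function(pair, encoder = mock_encoder()) {
  stopifnot(inherits(pair, "padded_chain_pair"), inherits(encoder, "encoder"))
  if (!identical(pair$pad_char, encoder$spec$pad_char))
    ab_stop("ab_pad_mismatch", sprintf(
      "pair padded with '%s' but encoder '%s' expects '%s'",
      pair$pad_char, encoder$spec$name, encoder$spec$pad_char))
  v <- encoder$encode(pair)
  if (length(v) != encoder$spec$total_features || !all(is.finite(v)))
    ab_stop("ab_dimension_mismatch", "encoder output violates its declared spec")
  structure(v, id = pair$id, encoder = encoder$spec$name)
}

#' Encode a list of paired antibodies into a feature matrix
#'
#' Numbers and pads each record once, then encodes; rows are named by record
#' id. Records that fail numbering are dropped and reported via the
#' `"failed"` attribute.
#'
#' @param records list of [paired_antibody()].
#' @param encoder an `encoder`.
#' @return numeric matrix (n x total_features).
#' @export
encode_records <- function(records, encoder = mock_encoder()) {
  rows <- list(); failed <- character(0)
  for (r in records) {
    v <- tryCatch({
      h <- number_chain(r$heavy); l <- number_chain(r$light)
      encode_pair(pad_pair(h, l, encoder$spec$pad_char), encoder)
    }, ab_error = function(e) NULL)
    if (is.null(v)) failed <- c(failed, r$id) else rows[[r$id]] <- v
  }
  m <- do.call(rbind, rows)
  structure(m, failed = failed)
}

#' Feature-index layout map
#'
#' Bijection from feature index to (chain, grid slot label, embedding
#' channel) for position-wise encoders, fixing the heavy-then-light,
#' position-major order. Used to attribute selected features to sequence
#' positions.
#'
#' @param encoder an `encoder` or `encoder_spec`.
#' @return data.frame with columns `index`, `chain`, `slot`, `channel`.
#' @export
layout_map <- function(encoder) {
  spec <- if (inherits(encoder, "encoder")) encoder$spec else encoder
  stopifnot(inherits(spec, "encoder_spec"))
  slots <- c(paste0("heavy:", grid_table("heavy")$label),
             paste0("light:", grid_table("light")$label))
  d <- spec$dim
  data.frame(index = seq_len(length(slots) * d),
             chain = rep(sub(":.*", "", slots), each = d),
             slot = rep(sub(".*:", "", slots), each = d),
             channel = rep(seq_len(d), times = length(slots)))
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
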