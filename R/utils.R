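#' Derive a deterministic sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from a single master seed through
#' named substreams (splits, permutations, simulation, inner folds), so
#' that unrelated stages never share or disturb each other's RNG state.
#' The derivation is a small polynomial rolling hash of the stream label
#' folded into the master seed, reduced modulo a prime below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stream character label of the substream.
#' @return an integer seed in [1, 2^31 - 1], deterministic in both inputs.
#' @export
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stream), length(stream) == 1L)
  m <- 2147483587  # prime < 2^31
  h <- as.double(abs(master_seed)) %% m
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(h) + 1L
}

#' Round half away from zero
#'
#' Plain rounding with ties going up (2.5 -> 3), unlike base [round()]
#' which rounds half to even. Used for the per-class train-set sizes in
#' stratified splitting so the rule is reproducible across platforms.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Hash a configuration object
#'
#' Serializes the object to canonical JSON and returns its MD5 digest.
#' Every output artifact of the pipeline embeds this hash so results can
#' be traced back to the exact configuration that produced them.
#'
#' @param config a list of configuration values (must be JSON-representable).
#' @return a 32-character hexadecimal string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

# shared argument checks ------------------------------------------------

assert_binary_labels <- function(labels) {
  if (!is.numeric(labels) || !all(labels %in% c(-1, 1)))
    stop("labels must be a numeric vector of +1/-1 values", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the labels", call. = FALSE)
  invisible(labels)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
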