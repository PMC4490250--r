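# Shared helpers: chromosome-name and coordinate conventions.
#
# Internal coordinates are 1-based inclusive throughout; BED/BEDPE I/O
# converts at the boundary.  Chromosome labels are stored without the "chr"
# prefix internally.

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that `"chr16"` and `"16"` compare equal.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector without the `"chr"` prefix.
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

# Detect whether two label sets mix "chr"-prefixed and bare conventions.
chrom_conventions_match <- function(a, b) {
  has_chr <- function(v) any(grepl("^chr", v))
  has_chr(a) == has_chr(b)
}

# BED/BEDPE (0-based half-open) -> internal (1-based inclusive)
bed_to_internal <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

internal_to_bed <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions -----------------------------------------------------

# LD is undefined at a monomorphic site; this is a distinct, catchable
# condition (not a numeric failure).
stop_monomorphic <- function(msg) {
  stop(errorCondition(msg, class = c("snphub_monomorphic", "snphub_error")))
}

stop_snphub <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "snphub_error")))
}

# Canonical unordered locus-pair key, used to merge duplicate edges.
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\r")
}

# Deterministic stage offsets: one user-facing seed drives every stage.
stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 0L, expression = 101L, contacts = 211L, scan = 307L)
  s <- as.integer(seed) + offs[[stage]]
  s %% .Machine$integer.max
}
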