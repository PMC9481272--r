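# Portable model archive: the fitted CSP bank and RLDA classifier are
# written as a single JSON document (full double precision, arrays stored
# with their dimensions), so archives are text, diffable and
# platform-independent.

ARCHIVE_VERSION <- "1"

arr_pack <- function(x) list(dim = dim(x) %||% length(x),
                             values = as.vector(x))
arr_unpack <- function(j) {
  v <- as.numeric(j$values)
  dm <- as.integer(unlist(j$dim))
  if (length(dm) > 1) array(v, dim = dm) else v
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a fitted model bundle to a JSON archive
#'
#' @param csp A fitted [fit_csp_bank()] model.
#' @param rlda A fitted [fit_rlda()] model.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
save_model_archive <- function(csp, rlda, path) {
  stopifnot(inherits(csp, "csp_bank"), inherits(rlda, "rlda"))
  doc <- list(
    format = "standbci-model", version = ARCHIVE_VERSION,
    bank = lapply(csp$bank$bands, as.numeric),
    csp = list(
      W_per_band = lapply(csp$W_per_band, arr_pack),
      eigvals_per_band = lapply(csp$eigvals_per_band, as.numeric),
      retained = csp$retained, n_retained = csp$n_retained,
      n_channels = csp$n_channels, channel_names = csp$channel_names),
    rlda = list(
      m1 = as.numeric(rlda$m1), m_neg1 = as.numeric(rlda$m_neg1),
      C1 = arr_pack(rlda$C1), C_neg1 = arr_pack(rlda$C_neg1),
      C_pooled = arr_pack(rlda$C_pooled),
      b = as.numeric(rlda$b), d = rlda$d,
      priors = as.numeric(rlda$priors),
      shrinkage = as.numeric(rlda$shrinkage)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model bundle from a JSON archive
#'
#' @param path Archive written by [save_model_archive()].
#' @return List with elements `csp` (a `csp_bank`) and `rlda` (an `rlda`).
#' @export
load_model_archive <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "standbci-model"))
    stop("not a model archive: ", path, call. = FALSE)
  bank <- filter_bank(lapply(doc$bank, as.numeric))
  csp <- structure(list(
    W_per_band = lapply(doc$csp$W_per_band, arr_unpack),
    eigvals_per_band = lapply(doc$csp$eigvals_per_band, as.numeric),
    retained = as.integer(unlist(doc$csp$retained)),
    n_retained = as.integer(doc$csp$n_retained),
    bank = bank,
    n_channels = as.integer(doc$csp$n_channels),
    channel_names = as.character(unlist(doc$csp$channel_names))),
    class = "csp_bank")
  rl <- doc$rlda
  rlda <- structure(list(
    m1 = as.numeric(unlist(rl$m1)), m_neg1 = as.numeric(unlist(rl$m_neg1)),
    C1 = arr_unpack(rl$C1), C_neg1 = arr_unpack(rl$C_neg1),
    C_pooled = arr_unpack(rl$C_pooled),
    b = as.numeric(unlist(rl$b)), d = as.numeric(rl$d),
    priors = stats::setNames(as.numeric(unlist(rl$priors)), c("1", "-1")),
    shrinkage = stats::setNames(as.numeric(unlist(rl$shrinkage)),
                                c("1", "-1"))),
    class = "rlda")
  list(csp = csp, rlda = rlda)
}
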