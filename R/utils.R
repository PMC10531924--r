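#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the simulators flows from one integer seed. Independent
#' random streams (system layout, base chemical shifts, measurement noise,
#' domain backgrounds, ...) are separated by hashing the master seed together
#' with a short stream label, so that e.g. regenerating noise never perturbs
#' the base shifts. The hash stays below 2^31 - 1 so it is always a valid R
#' seed.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, "hsqc-noise")
split_seed <- function(seed, stream) {
  if (length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer")
  }
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' The standard 20-letter amino-acid alphabet
#'
#' @return Character vector of the 20 one-letter residue codes,
#'   alphabetical.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Path to a bundled example data file
#'
#' The package ships the entolysin worked example as plain-text inputs: the
#' NRPS descriptor derived from its biosynthetic gene cluster and the Marfey's
#' composition tables of its two diastereomeric products.
#'
#' @param file File name; `NULL` lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' clipstereo_example()
#' clipstereo_example("entolysin_nrps.tsv")
clipstereo_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "clipstereo")))
  }
  path <- system.file("extdata", file, package = "clipstereo")
  if (!nzchar(path)) {
    abort(sprintf("no example file '%s'; see clipstereo_example()", file))
  }
  path
}
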