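CDOMAIN_TYPES <- c("CSTART", "EC", "LCL")
EPI_LABELS <- c("ACTIVE", "INACTIVE", "INTERMITTENT", "UNKNOWN")

#' Describe an NRPS assembly line
#'
#' An `nrps_system` is an ordered set of modules, one per incorporated
#' residue. Each module records the residue class proposed for its A-domain
#' (pooled classes such as `Glx` or `Xle` are legal names) and the type of
#' its condensation domain: `CSTART` (the initial fatty-acid loading
#' C-domain, module 1 only), `EC` (dual epimerization/condensation) or
#' `LCL` (condensation-only). E/C modules may additionally carry an
#' epimerization-activity label (`ACTIVE`, `INACTIVE`, `INTERMITTENT` or
#' `UNKNOWN`, typically derived from homology to domains with experimentally
#' established behaviour); non-E/C modules carry none.
#'
#' @param modules A data frame with columns `index` (1-based, contiguous),
#'   `residue`, `cdomain` and optionally `epi_label`.
#' @param macrocycle_size Number of residues in the ester-closed macrocycle
#'   (the `m` of the `(l:m)` CLiP tag). Metadata only: cyclization does not
#'   enter the configuration logic. Defaults to the number of modules.
#' @param name Optional free-text name.
#' @return A tibble of modules with class `nrps_system` and attributes
#'   `macrocycle_size` and `name`.
#' @seealso [read_nrps()], [predict_configurations()],
#'   [derive_hard_constraints()]
#' @export
#' @examples
#' nrps_system(data.frame(
#'   index = 1:3, residue = c("Leu", "Glu", "Ser"),
#'   cdomain = c("CSTART", "EC", "LCL")
#' ))
nrps_system <- function(modules, macrocycle_size = NULL, name = NULL) {
  modules <- tibble::as_tibble(modules)
  missing_fields <- setdiff(c("index", "residue", "cdomain"), names(modules))
  if (length(missing_fields)) {
    abort(sprintf("NRPS descriptor is missing field(s): %s",
                  paste(missing_fields, collapse = ", ")))
  }
  if (!"epi_label" %in% names(modules)) modules$epi_label <- NA_character_
  modules <- modules[c("index", "residue", "cdomain", "epi_label")]

  suppressWarnings(modules$index <- as.integer(modules$index))
  if (anyNA(modules$index)) abort("field 'index' must be an integer for every module")
  modules$residue <- as.character(modules$residue)
  modules$cdomain <- toupper(as.character(modules$cdomain))
  modules$epi_label <- toupper(as.character(modules$epi_label))
  modules <- modules[order(modules$index), ]

  n <- nrow(modules)
  if (n < 1L) abort("an NRPS system needs at least one module")
  dup <- modules$index[duplicated(modules$index)]
  if (length(dup)) abort(sprintf("duplicate module index: %d", dup[1]))
  if (!identical(modules$index, seq_len(n))) {
    abort(sprintf("module indices must run 1..%d without gaps (field 'index')", n))
  }
  if (anyNA(modules$residue) || any(!nzchar(modules$residue))) {
    abort("field 'residue' must be nonempty for every module")
  }
  bad <- which(!modules$cdomain %in% CDOMAIN_TYPES)
  if (length(bad)) {
    abort(sprintf("module %d: unknown cdomain '%s' (expected CSTART, EC or LCL)",
                  bad[1], modules$cdomain[bad[1]]))
  }
  if (modules$cdomain[1] != "CSTART") {
    abort("module 1 must carry the fatty-acid loading C-domain (cdomain = CSTART)")
  }
  if (any(modules$cdomain[-1] == "CSTART")) {
    abort("CSTART is only valid for module 1")
  }

  is_ec <- modules$cdomain == "EC"
  blank <- is.na(modules$epi_label) | !nzchar(modules$epi_label)
  modules$epi_label[is_ec & blank] <- "UNKNOWN"
  bad_lab <- which(is_ec & !modules$epi_label %in% EPI_LABELS)
  if (length(bad_lab)) {
    abort(sprintf("module %d: unknown epi_label '%s'",
                  bad_lab[1], modules$epi_label[bad_lab[1]]))
  }
  modules$epi_label[!is_ec] <- NA_character_  # labels are E/C-only

  m <- as.integer(macrocycle_size %||% n)
  if (is.na(m) || m < 1L || m > n) {
    abort("macrocycle_size must satisfy 0 < m <= number of modules")
  }

  structure(modules,
            class = c("nrps_system", class(tibble::tibble())),
            macrocycle_size = m,
            name = as.character(name %||% ""))
}

#' @export
print.nrps_system <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<nrps_system>%s %d modules, (%d:%d) tag\n",
              if (nzchar(nm)) paste0(" ", nm, ":") else "",
              nrow(x), nrow(x), attr(x, "macrocycle_size")))
  print(tibble::new_tibble(as.list(x), nrow = nrow(x)), ...)
  invisible(x)
}

#' Read / write an NRPS descriptor file
#'
#' Two on-disk forms are supported. A TSV with header columns `index`,
#' `residue`, `cdomain`, `epi_label` (the label column may be omitted or
#' left as `NA`/`.` for non-E/C modules) and optional metadata comment lines
#' `# name: ...` / `# macrocycle_size: ...`; or a JSON document with fields
#' `name`, `macrocycle_size` and a `modules` array of the same records.
#' The format is picked from the file extension (`.json` vs anything else).
#'
#' @param path File path.
#' @return `read_nrps()` returns a validated [nrps_system()];
#'   `write_nrps()` returns `path` invisibly. `write_nrps(read_nrps(f))`
#'   round-trips to an identical system.
#' @export
read_nrps <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such NRPS descriptor: '%s'", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$modules)) abort("JSON NRPS descriptor needs a 'modules' array")
    return(nrps_system(doc$modules, doc$macrocycle_size, doc$name))
  }
  lines <- readLines(path, warn = FALSE)
  meta_raw <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_raw) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) abort(sprintf("'%s': no module records found", path))
  tbl <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         na = c("", "NA", "."),
                         col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE)
  nrps_system(tbl,
              macrocycle_size = meta$macrocycle_size,
              name = meta$name)
}

#' @param system An [nrps_system()].
#' @rdname read_nrps
#' @export
write_nrps <- function(system, path) {
  stopifnot(inherits(system, "nrps_system"))
  tbl <- tibble::new_tibble(as.list(system), nrow = nrow(system))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(name = attr(system, "name"),
           macrocycle_size = attr(system, "macrocycle_size"),
           modules = tbl),
      path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  } else {
    header <- c(
      if (nzchar(attr(system, "name"))) sprintf("# name: %s", attr(system, "name")),
      sprintf("# macrocycle_size: %d", attr(system, "macrocycle_size")))
    writeLines(header, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, na = "NA")
  }
  invisible(path)
}

#' Predict per-residue configuration from C-domain architecture
#'
#' The configuration of residue `i` is set by the condensation domain of
#' module `i + 1`, which condenses the next residue onto the chain and, if it
#' is a dual E/C domain, epimerizes residue `i` from L to D. An LCL domain in
#' module `i + 1` leaves residue `i` in the L form. The final residue has no
#' downstream C-domain before thioesterase release and is always predicted L.
#' Epimerization-activity labels are deliberately ignored here: this is the
#' naive architecture rule, against which Marfey's data and activity priors
#' are later weighed (see [derive_hard_constraints()]).
#'
#' @param system An [nrps_system()].
#' @return A tibble with columns `position`, `residue`, `configuration`
#'   (`"D"` or `"L"`).
#' @export
#' @examples
#' sys <- read_nrps(clipstereo_example("entolysin_nrps.tsv"))
#' predict_configurations(sys)
predict_configurations <- function(system) {
  stopifnot(inherits(system, "nrps_system"))
  n <- nrow(system)
  downstream <- system$cdomain[-1]
  configuration <- c(ifelse(downstream == "EC", "D", "L"), "L")
  tibble(position = seq_len(n),
         residue = system$residue,
         configuration = configuration)
}

#' Length of the C-domain run following the loading domain
#'
#' Counts how many consecutive C-domains of one type immediately follow the
#' initial CSTART domain, e.g. the run of ten E/C domains that opens the
#' entolysin assembly line.
#'
#' @param system An [nrps_system()].
#' @param dtype `"EC"` or `"LCL"`.
#' @return An integer run length (0 when the first elongation module is of
#'   the other type).
#' @export
count_domain_run <- function(system, dtype = c("EC", "LCL")) {
  stopifnot(inherits(system, "nrps_system"))
  dtype <- match.arg(toupper(dtype[1]), c("EC", "LCL"))
  downstream <- system$cdomain[-1]
  if (!length(downstream) || downstream[1] != dtype) return(0L)
  as.integer(rle(downstream)$lengths[1])
}

#' Attach epimerization-activity labels to E/C modules
#'
#' @param system An [nrps_system()].
#' @param labels A data frame with columns `index` and `epi_label`; only
#'   E/C modules are updated.
#' @return The relabelled system.
#' @export
apply_epi_labels <- function(system, labels) {
  stopifnot(inherits(system, "nrps_system"))
  labels <- tibble::as_tibble(labels)
  i <- match(labels$index, system$index)
  if (anyNA(i)) abort("labels refer to module indices absent from the system")
  tbl <- tibble::new_tibble(as.list(system), nrow = nrow(system))
  tbl$epi_label[i] <- toupper(labels$epi_label)
  nrps_system(tbl, attr(system, "macrocycle_size"), attr(system, "name"))
}
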