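#' Landmark scheme: fixed landmarks plus sliding semilandmark curves
#'
#' A scheme declares the correspondence contract every configuration must
#' satisfy: how many fixed (homologous) landmarks there are, and which
#' landmark ids form each semilandmark curve. Curve anchors are fixed
#' landmarks; the semilandmarks between them have no point-to-point homology
#' and are slid along the curve during superimposition.
#'
#' Ids are 1-based everywhere in R code and in files; every id in
#' `1:total` is either fixed or belongs to exactly one curve.
#'
#' @param n_fixed number of fixed landmarks; fixed ids are `1:n_fixed`.
#' @param curves list of curves, each a list with elements `start` (anchor
#'   fixed-landmark id), `semis` (ordered integer vector of semilandmark
#'   ids) and `end` (anchor fixed-landmark id).
#' @return an object of class `landmark_scheme` with elements `n_fixed`,
#'   `curves`, `total` (total landmark count) and `semis` (all semilandmark
#'   ids).
#' @examples
#' sc <- landmark_scheme(3, list(list(start = 1, semis = 4:6, end = 2)))
#' sc$total  # 6
#' @export
landmark_scheme <- function(n_fixed, curves = list()) {
  n_fixed <- as.integer(n_fixed)
  if (n_fixed < 1) stop("scheme needs at least one fixed landmark")
  semis <- integer(0)
  for (cv in curves) {
    if (!all(c("start", "semis", "end") %in% names(cv)))
      stop("each curve needs 'start', 'semis' and 'end'")
    if (cv$start > n_fixed || cv$end > n_fixed)
      stop("curve anchors must be fixed-landmark ids (<= n_fixed)")
    if (length(cv$semis) < 1) stop("curve with no semilandmarks")
    semis <- c(semis, as.integer(cv$semis))
  }
  if (anyDuplicated(semis))
    stop("semilandmark id assigned to more than one curve: ",
         paste(unique(semis[duplicated(semis)]), collapse = ", "))
  if (any(semis <= n_fixed))
    stop("semilandmark ids must be greater than n_fixed")
  total <- n_fixed + length(semis)
  ids <- sort(c(seq_len(n_fixed), semis))
  if (!identical(ids, seq_len(total)))
    stop("ids must cover 1..total with no gaps")
  structure(list(n_fixed = n_fixed, curves = curves,
                 total = total, semis = sort(semis), dimension = 3L),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_fixed, "fixed +", length(x$semis),
      "sliding semilandmarks on", length(x$curves), "curve(s);",
      x$total, "landmarks total (3D)\n")
  invisible(x)
}

#' Default landmark scheme used by the synthetic-data generator
#'
#' Mimics a cranial-element template of 15 fixed landmarks and 40
#' semilandmarks equally distributed over 4 curves (10 each), 55 landmarks
#' in total.
#' @return a [landmark_scheme()].
#' @export
default_scheme <- function() {
  landmark_scheme(15L, list(
    list(start = 1L,  semis = 16:25, end = 4L),
    list(start = 4L,  semis = 26:35, end = 8L),
    list(start = 8L,  semis = 36:45, end = 12L),
    list(start = 12L, semis = 46:55, end = 1L)))
}

#' Read or write a landmark scheme as JSON
#'
#' The JSON carrier stores `{n_fixed, curves:[{start, semis:[...], end}]}`.
#' @param path file path.
#' @param scheme a [landmark_scheme()].
#' @return `read_scheme_json` returns a `landmark_scheme`;
#'   `write_scheme_json` returns `path` invisibly.
#' @export
read_scheme_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  curves <- lapply(j$curves, function(cv)
    list(start = as.integer(cv$start), semis = as.integer(unlist(cv$semis)),
         end = as.integer(cv$end)))
  landmark_scheme(j$n_fixed, curves)
}

#' @rdname read_scheme_json
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(list(n_fixed = scheme$n_fixed,
                            curves = scheme$curves),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a single landmark configuration
#'
#' One digitized element: a K x 3 coordinate matrix plus specimen metadata.
#'
#' @param coords numeric K x 3 matrix in digitization units.
#' @param specimen_id,species,genus character metadata.
#' @param side one of `"left"`, `"right"`, `"unknown"`.
#' @param era one of `"modern"`, `"subfossil"`.
#' @param scheme the [landmark_scheme()] the coordinates follow.
#' @return an object of class `configuration`.
#' @export
configuration <- function(coords, specimen_id, species = NA_character_,
                          genus = NA_character_, side = "unknown",
                          era = "modern", scheme = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be K x 3")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in specimen ", specimen_id)
  if (!is.null(scheme) && nrow(coords) != scheme$total)
    stop("specimen ", specimen_id, ": ", nrow(coords),
         " landmarks but scheme declares ", scheme$total)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0))
    stop("specimen ", specimen_id, ": exactly coincident landmarks")
  side <- match.arg(side, c("left", "right", "unknown"))
  era <- match.arg(era, c("modern", "subfossil"))
  structure(list(coords = coords, specimen_id = as.character(specimen_id),
                 species = species, genus = genus, side = side, era = era),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("Configuration %s (%s, %s %s): %d landmarks\n",
              x$specimen_id,
              if (is.na(x$species)) "sp. indet." else x$species,
              x$era, x$side, nrow(x$coords)))
  invisible(x)
}

# internal: metadata of a list of configurations as a data.frame
config_metadata <- function(configs) {
  data.frame(
    specimen_id = vapply(configs, `[[`, "", "specimen_id"),
    species = vapply(configs, `[[`, "", "species"),
    genus = vapply(configs, `[[`, "", "genus"),
    side = vapply(configs, `[[`, "", "side"),
    era = vapply(configs, `[[`, "", "era"),
    stringsAsFactors = FALSE)
}
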