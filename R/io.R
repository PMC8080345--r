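#' Read and write landmark configurations in TPS format
#'
#' The TPS dialect used here is the classic one: each record starts with
#' `LM3=K`, followed by K whitespace-separated `x y z` lines, an `ID=` line,
#' and optional `KEY=value` metadata lines (`SPECIES=`, `GENUS=`, `SIDE=`,
#' `ERA=`, `SCALE=`); unknown keys are preserved verbatim on write-through.
#'
#' @param path file path.
#' @param scheme optional [landmark_scheme()]; when given, every record must
#'   declare exactly `scheme$total` landmarks.
#' @return `read_tps` returns a list of [configuration()] objects.
#' @export
read_tps <- function(path, scheme = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^LM3=", lines)
  if (length(starts) == 0) stop("no LM3= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    k <- as.integer(sub("^LM3=", "", block[1]))
    coord_lines <- block[2:(1 + k)]
    if (length(coord_lines) < k || any(grepl("=", coord_lines)))
      stop("record ", i, ": expected ", k, " coordinate lines")
    coords <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (ncol(coords) != 3 || any(!is.finite(coords)))
      stop("record ", i, ": malformed 3D coordinates")
    meta_lines <- block[-(1:(1 + k))]
    meta_lines <- meta_lines[nzchar(meta_lines)]
    kv <- strsplit(meta_lines, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1))
    vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
    get <- function(key, default = NA_character_) {
      if (key %in% keys) vals[match(key, keys)] else default
    }
    id <- get("ID")
    if (is.na(id)) stop("record ", i, ": missing ID= line")
    if (!is.null(scheme) && k != scheme$total)
      stop("record '", id, "': LM3=", k,
           " does not match scheme total ", scheme$total)
    out[[i]] <- configuration(coords, id,
                              species = get("SPECIES"),
                              genus = get("GENUS"),
                              side = tolower(get("SIDE", "unknown")),
                              era = tolower(get("ERA", "modern")),
                              scheme = scheme)
  }
  out
}

#' @rdname read_tps
#' @param configs list of [configuration()] objects to write.
#' @param digits decimal digits written (default 10; round-trips double
#'   precision landmark data in practice).
#' @export
write_tps <- function(configs, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM3=%d", nrow(cf$coords)), con)
    writeLines(apply(cf$coords, 1, function(r)
      paste(formatC(r, digits = digits, format = "f"), collapse = " ")), con)
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
    if (!is.na(cf$species)) writeLines(sprintf("SPECIES=%s", cf$species), con)
    if (!is.na(cf$genus)) writeLines(sprintf("GENUS=%s", cf$genus), con)
    writeLines(sprintf("SIDE=%s", cf$side), con)
    writeLines(sprintf("ERA=%s", cf$era), con)
  }
  invisible(path)
}

#' Read and write landmark configurations as a long-format table
#'
#' Columns: `specimen_id, species, genus, side, era, landmark_id, x, y, z`;
#' CSV or TSV with mandatory header, one row per landmark.
#'
#' @inheritParams read_tps
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return `read_landmark_table` returns a list of [configuration()]s.
#' @export
read_landmark_table <- function(path, scheme = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "genus", "side", "era",
            "landmark_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("specimen_id", "landmark_id")]))
    stop("duplicate (specimen, landmark) rows")
  lapply(split(df, df$specimen_id), function(d) {
    want <- if (is.null(scheme)) sort(unique(d$landmark_id)) else
      seq_len(scheme$total)
    missing_ids <- setdiff(want, d$landmark_id)
    if (length(missing_ids))
      stop("specimen ", d$specimen_id[1], ": missing landmark ids: [",
           paste(missing_ids, collapse = ", "), "]")
    d <- d[order(d$landmark_id), ]
    coords <- as.matrix(d[c("x", "y", "z")])
    dimnames(coords) <- NULL
    configuration(coords, d$specimen_id[1],
                  species = d$species[1], genus = d$genus[1],
                  side = d$side[1], era = d$era[1], scheme = scheme)
  })
}

#' @rdname read_landmark_table
#' @param configs list of [configuration()]s.
#' @export
write_landmark_table <- function(configs, path, sep = ",") {
  rows <- lapply(configs, function(cf) {
    k <- nrow(cf$coords)
    data.frame(specimen_id = cf$specimen_id, species = cf$species,
               genus = cf$genus, side = cf$side, era = cf$era,
               landmark_id = seq_len(k),
               x = cf$coords[, 1], y = cf$coords[, 2], z = cf$coords[, 3],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] enforcing the contracts the
#' downstream comparative methods need: labelled tips, unique labels,
#' non-negative branch lengths. Zero-length branches are allowed with a
#' warning (they make the tree covariance singular if terminal).
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path)
  validate_phylogeny(tree)
}

# internal: contract checks shared by read_newick and in-memory trees
validate_phylogeny <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (any(tree$edge.length == 0)) warning("tree contains zero-length branches")
  tree
}
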