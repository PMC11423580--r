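#' Read an extended-XYZ file
#'
#' Extended XYZ: per frame, an atom-count line, a comment line of
#' `key=value` pairs (values may be double-quoted; `Lattice` and `Properties`
#' are preserved like any other key), then one line per atom with the species
#' symbol and three Cartesian coordinates (length units as written, typically
#' Angstrom-like). Multi-frame files yield a trajectory in file order.
#'
#' @param path file path.
#' @return list of structures: `list(species, positions, comment, fields)`
#'   where `fields` is the parsed named character vector of comment-line
#'   key=value pairs.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed extended-XYZ header at line ", i,
           ": expected an atom count, got '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated frame at line ", i, ": header declares ", n,
           " atoms but the file ends early")
    comment <- lines[i + 1L]
    atoms <- lines[(i + 2L):(i + 1L + n)]
    sp <- character(n)
    pos <- matrix(NA_real_, n, 3)
    for (a in seq_len(n)) {
      tok <- strsplit(trimws(atoms[a]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop("malformed atom line ", i + 1L + a, ": '", atoms[a], "'")
      sp[a] <- tok[1]
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        stop("non-numeric coordinates at line ", i + 1L + a)
      pos[a, ] <- xyz
    }
    frames[[length(frames) + 1L]] <-
      list(species = sp, positions = pos, comment = comment,
           fields = parse_xyz_comment(comment))
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  frames
}

parse_xyz_comment <- function(comment) {
  fields <- character(0)
  s <- comment
  pat <- '^\\s*([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|\\S+)'
  while (grepl(pat, s)) {
    m <- regmatches(s, regexec(pat, s))[[1]]
    val <- if (nzchar(m[4]) || grepl('^"', m[3])) m[4] else m[3]
    fields[m[2]] <- val
    s <- sub(pat, "", s)
  }
  fields
}

#' Write structures to an extended-XYZ file
#'
#' @param structures a structure or list of structures
#'   (`list(species, positions, comment)`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structures, path) {
  if (!is.null(structures$positions)) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    n <- nrow(s$positions)
    writeLines(as.character(n), con)
    writeLines(if (is.null(s$comment)) "" else s$comment, con)
    for (a in seq_len(n))
      writeLines(sprintf("%s %.17g %.17g %.17g", s$species[a],
                         s$positions[a, 1], s$positions[a, 2],
                         s$positions[a, 3]), con)
  }
  invisible(path)
}

CONTAINER_VERSION <- "1"

num_fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Write a feature container
#'
#' A feature container is a directory of plain-text tables plus JSON metadata:
#' `features.csv` (the environment feature matrix), `envmap.csv` (0-based
#' structure index per environment), `blocks.csv` (label and 0-based half-open
#' column range per component block, if any), `gradients.csv` (long-format
#' nonzero gradient entries, if any), `targets.csv` (kind, weight, value,
#' 0-based structure id, grad columns, if any), and `meta.json` (format
#' version, indexing convention, seed, units). All indices on disk are
#' 0-based; the R API is 1-based and conversion happens here. Numbers are
#' written with 17 significant digits, so a read/write round trip is
#' bit-exact.
#'
#' @param fs a [feature_set()].
#' @param path directory to create/write.
#' @param targets optional list of valued [target_row()]s with an optional
#'   `structure_id` attribute each.
#' @param seed optional integer recorded in the metadata.
#' @param units optional unit note recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_container <- function(fs, path, targets = NULL, seed = NA,
                            units = "unitless") {
  stopifnot(inherits(fs, "feature_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  X <- fs$env_features
  write.table(matrix(num_fmt(X), nrow(X), ncol(X)),
              file.path(path, "features.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(structure = fs$structure_of_env - 1L),
                   file.path(path, "envmap.csv"), row.names = FALSE)
  if (!is.null(fs$blocks)) {
    bdf <- data.frame(label = names(fs$blocks),
                      start = vapply(fs$blocks, function(b) b[1] - 1L, 0L),
                      stop = vapply(fs$blocks, function(b) b[2], 0L))
    utils::write.csv(bdf, file.path(path, "blocks.csv"), row.names = FALSE)
  }
  if (!is.null(fs$env_gradients)) {
    gr <- fs$env_gradients
    nz <- which(gr != 0, arr.ind = TRUE)
    gdf <- data.frame(env = nz[, 1] - 1L, coord = nz[, 2] - 1L,
                      feature = nz[, 3] - 1L,
                      value = num_fmt(gr[nz]))
    gdf <- gdf[order(gdf$env, gdf$coord, gdf$feature), ]
    utils::write.csv(gdf, file.path(path, "gradients.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(targets)) {
    tdf <- data.frame(
      kind = vapply(targets, function(r) r$kind, ""),
      weight = num_fmt(vapply(targets, function(r) r$weight, 0)),
      value = num_fmt(vapply(targets, function(r) r$value, 0)),
      structure = vapply(targets, function(r) {
        sid <- attr(r, "structure_id")
        if (is.null(sid)) NA_integer_ else as.integer(sid) - 1L
      }, 0L))
    G <- t(vapply(targets, function(r) r$grad_w,
                  numeric(length(targets[[1]]$grad_w))))
    gcols <- as.data.frame(matrix(num_fmt(G), nrow(G), ncol(G)))
    names(gcols) <- paste0("g", seq_len(ncol(G)) - 1L)
    utils::write.csv(cbind(tdf, gcols), file.path(path, "targets.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- list(format = "rigidr-feature-container",
               format_version = CONTAINER_VERSION,
               indexing = "0-based",
               n_env = nrow(X), n_features = ncol(X),
               n_coords = if (is.null(fs$env_gradients)) 0L
                          else dim(fs$env_gradients)[2],
               seed = seed, units = units)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature container
#'
#' @param path container directory written by [write_container()].
#' @return list with `featureset` (a [feature_set()]) and `targets` (list of
#'   [target_row()]s, or `NULL`), plus `meta`.
#' @export
read_container <- function(path) {
  metafile <- file.path(path, "meta.json")
  if (!file.exists(metafile))
    stop("missing mandatory dataset: meta.json (not a feature container?)")
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), CONTAINER_VERSION))
    stop("container format version mismatch: file has '",
         meta$format_version, "', this reader expects '",
         CONTAINER_VERSION, "'")
  ffile <- file.path(path, "features.csv")
  if (!file.exists(ffile)) stop("missing mandatory dataset: features.csv")
  X <- as.matrix(utils::read.csv(ffile, header = FALSE))
  dimnames(X) <- NULL
  efile <- file.path(path, "envmap.csv")
  if (!file.exists(efile)) stop("missing mandatory dataset: envmap.csv")
  som <- utils::read.csv(efile)$structure + 1L
  blocks <- NULL
  bfile <- file.path(path, "blocks.csv")
  if (file.exists(bfile)) {
    bdf <- utils::read.csv(bfile)
    blocks <- stats::setNames(
      lapply(seq_len(nrow(bdf)), function(i)
        c(bdf$start[i] + 1L, bdf$stop[i])),
      bdf$label)
  }
  gr <- NULL
  gfile <- file.path(path, "gradients.csv")
  if (file.exists(gfile)) {
    gdf <- utils::read.csv(gfile)
    gr <- array(0, dim = c(meta$n_env, meta$n_coords, meta$n_features))
    gr[cbind(gdf$env + 1L, gdf$coord + 1L, gdf$feature + 1L)] <- gdf$value
  }
  fs <- feature_set(X, som, blocks = blocks, env_gradients = gr)
  targets <- NULL
  tfile <- file.path(path, "targets.csv")
  if (file.exists(tfile)) {
    tdf <- utils::read.csv(tfile)
    gcols <- grep("^g[0-9]+$", names(tdf), value = TRUE)
    gcols <- gcols[order(as.integer(sub("^g", "", gcols)))]
    targets <- lapply(seq_len(nrow(tdf)), function(i) {
      r <- target_row(as.numeric(tdf[i, gcols]), weight = tdf$weight[i],
                      kind = tdf$kind[i], value = tdf$value[i])
      if (!is.na(tdf$structure[i]))
        attr(r, "structure_id") <- tdf$structure[i] + 1L
      r
    })
  }
  list(featureset = fs, targets = targets, meta = meta)
}
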