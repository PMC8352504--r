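#' Read RNA sequences from a FASTA file
#'
#' Multi-record FASTA; `T` is normalised to `U` and lowercase is uppercased.
#'
#' @param path FASTA file.
#' @return A list of [rna()] objects, named by record id.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(k)
    rna(as.character(set[[k]]), id = names(set)[k]))
  names(out) <- names(set)
  out
}

#' Read / write structure lists
#'
#' The on-disk dialect is one `dot-bracket<TAB>energy` line per structure
#' (energy in kcal/mol, two decimals on writing), preceded by `#` comment
#' headers. Readers skip comments, accept whitespace-separated extra
#' columns, and tolerate a missing energy column, so structure lists
#' produced by other sampling tools can be scored directly.
#'
#' @param path File path.
#' @return `read_structure_list`: a `data.frame` with columns `db` and
#'   `energy` (`NA` where absent) and a `count` column when duplicate lines
#'   occur.
#' @export
read_structure_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(db = character(0), energy = numeric(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  db <- vapply(parts, `[[`, character(1), 1L)
  energy <- vapply(parts, function(p)
    if (length(p) >= 2L) suppressWarnings(as.numeric(p[2L])) else NA_real_,
    numeric(1))
  agg <- data.frame(db = db, energy = energy, stringsAsFactors = FALSE)
  tab <- table(agg$db)
  agg <- agg[!duplicated(agg$db), , drop = FALSE]
  agg$count <- as.integer(tab[agg$db])
  rownames(agg) <- NULL
  agg
}

#' @rdname read_structure_list
#' @param x A `sample_set` or a `data.frame` with columns `db`, `energy`
#'   and optionally `count` (rows are repeated `count` times on writing).
#' @param header Named list written as `# key: value` comment lines (e.g.
#'   seed and configuration hash).
#' @export
write_structure_list <- function(x, path, header = list()) {
  if (inherits(x, "sample_set")) {
    df <- x$draws
    df$energy <- NA_real_
    header <- c(list(seed = x$seed, source = x$source), header)
    x <- df
  }
  stopifnot(is.data.frame(x), "db" %in% names(x))
  if (!"count" %in% names(x)) x$count <- 1L
  if (!"energy" %in% names(x)) x$energy <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header)) {
    writeLines(paste0("# ", nm, ": ", header[[nm]]), con)
  }
  for (k in seq_len(nrow(x))) {
    line <- if (is.na(x$energy[k])) x$db[k] else
      paste0(x$db[k], "\t", sprintf("%.2f", x$energy[k]))
    writeLines(rep(line, x$count[k]), con)
  }
  invisible(path)
}

#' Export a barrier tree
#'
#' Two formats: a `barriers`-style text table (index, dot-bracket, energy,
#' father index, barrier height) and a JSON document with the full merge
#' list.
#'
#' @param tree A [barrier_tree()].
#' @param path Output file.
#' @export
write_barrier_tree <- function(tree, path) {
  stopifnot(inherits(tree, "barrier_tree"))
  lv <- tree$leaves
  id <- stats::setNames(seq_len(nrow(lv)), lv$db)
  father <- rep(0L, nrow(lv))
  barrier <- rep(NA_real_, nrow(lv))
  if (nrow(tree$merges) > 0L) {
    for (r in order(tree$merges$saddle_energy)) {
      shallow <- tree$merges$right_db[r]
      deep <- tree$merges$left_db[r]
      k <- id[[shallow]]
      if (is.na(barrier[k])) {
        father[k] <- id[[deep]]
        barrier[k] <- tree$merges$saddle_energy[r] - lv$energy[k]
      }
    }
  }
  out <- data.frame(index = seq_len(nrow(lv)), structure = lv$db,
                    energy = round(lv$energy, 2), father = father,
                    barrier = round(barrier, 2), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barrier_tree
#' @export
write_barrier_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "barrier_tree"))
  jsonlite::write_json(list(leaves = tree$leaves, merges = tree$merges,
                            merge_threshold = tree$merge_threshold,
                            band = tree$band),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# JSON-lines logging for pipeline runs
write_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
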