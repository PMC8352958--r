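# Plain-text I/O: TSV profile matrices with provenance headers, GMT pathway
# files, long-form read-mapping tables, clinical tables and JSON manifests.
# All files are UTF-8 TSV; provenance lines start with '#'.

.write_header <- function(con, provenance) {
  for (nm in names(provenance)) {
    writeLines(sprintf("#%s: %s", nm, provenance[[nm]]), con)
  }
}

.read_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  prov <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    i <- regexpr(": ", kv, fixed = TRUE)
    if (i > 0) prov[[substr(kv, 1, i - 1)]] <- substr(kv, i + 2, nchar(kv))
  }
  list(provenance = prov, n_skip = length(hdr))
}

#' Write / read a profile matrix as TSV
#'
#' Files store features in rows and samples in columns, with a header row of
#' sample ids and optional `#key: value` provenance lines.
#'
#' @param profile an [abundance_profile()] (or samples x features matrix).
#' @param path file path.
#' @param provenance named list written as `#`-prefixed header lines; the
#'   profile level is always recorded.
#' @return `write_profile`: the path, invisibly. `read_profile`: an
#'   `abundance_profile` (empty when the file holds no features).
#' @export
write_profile <- function(profile, path, provenance = list()) {
  mat <- as_profile_matrix(profile)
  level <- if (inherits(profile, "abundance_profile")) profile$level else "gene"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  .write_header(con, c(list(level = level), provenance))
  tab <- t(mat)
  writeLines(paste(c("feature", colnames(tab)), collapse = "\t"), con)
  if (nrow(tab)) {
    body <- apply(tab, 1, function(r) paste(r, collapse = "\t"))
    writeLines(paste(rownames(tab), body, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  hdr <- .read_header(path)
  level <- hdr$provenance$level %||% "gene"
  first <- readLines(path, warn = FALSE)[hdr$n_skip + 1]
  if (is.na(first) || !nzchar(first)) {
    return(abundance_profile(matrix(numeric(0), 0, 0), level))
  }
  samples <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
  tab <- utils::read.table(path, sep = "\t", skip = hdr$n_skip + 1,
                           header = FALSE, row.names = 1,
                           col.names = c("feature", samples),
                           check.names = FALSE, comment.char = "")
  if (nrow(tab) == 0) {
    return(abundance_profile(matrix(numeric(0), length(samples), 0,
                                    dimnames = list(samples, NULL)), level))
  }
  mat <- t(as.matrix(tab))
  rownames(mat) <- samples
  abundance_profile(mat, level)
}

#' Write / read GMT pathway membership files
#'
#' One pathway per line: id, description, then tab-separated member KO ids.
#' Duplicate pathway ids are an error on read.
#'
#' @param pathways named list of KO-id character vectors.
#' @param path file path.
#' @param descriptions optional character vector parallel to `pathways`.
#' @return `write_gmt`: the path, invisibly. `read_gmt`: named list of KO-id
#'   vectors with a `descriptions` attribute.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("-", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop_invalid("malformed GMT line(s): %s", paste(bad, collapse = ", "))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_invalid("duplicate pathway id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- ids
  attr(out, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  out
}

#' Write / read read-mapping tables (long TSV)
#'
#' Columns: `sample_id`, `gene_set` (comma-joined gene ids), `count`,
#' `is_unique` (1 for unique reads, 0 for multi-read groups).
#'
#' @param samples list of [read_map_sample()]s.
#' @param path file path.
#' @return `write_readmap`: the path, invisibly. `read_readmap`: a named
#'   list of `read_map_sample`s.
#' @export
write_readmap <- function(samples, path) {
  rows <- list("sample_id\tgene_set\tcount\tis_unique")
  for (s in samples) {
    if (length(s$unique_counts)) {
      rows[[length(rows) + 1L]] <- paste(s$sample_id,
                                         names(s$unique_counts),
                                         s$unique_counts, 1L, sep = "\t")
    }
    for (g in s$multi_groups) {
      rows[[length(rows) + 1L]] <- paste(s$sample_id,
                                         paste(g$genes, collapse = ","),
                                         g$count, 0L, sep = "\t")
    }
  }
  writeLines(unlist(rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_readmap
#' @export
read_readmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "gene_set", "count", "is_unique")
  if (!all(need %in% names(tab))) {
    stop_invalid("readmap file lacks columns: %s",
                 paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- list()
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, , drop = FALSE]
    u <- sub[sub$is_unique == 1, , drop = FALSE]
    m <- sub[sub$is_unique == 0, , drop = FALSE]
    groups <- lapply(seq_len(nrow(m)), function(i) {
      list(genes = strsplit(m$gene_set[i], ",", fixed = TRUE)[[1]],
           count = m$count[i])
    })
    out[[sid]] <- read_map_sample(sid,
                                  stats::setNames(u$count, u$gene_set),
                                  groups)
  }
  out
}

#' Write / read a gene catalog as TSV
#' @param catalog a `gene_catalog`.
#' @param path file path.
#' @return `write_catalog`: path, invisibly; `read_catalog`: a
#'   `gene_catalog` (paralog families and pathways are not round-tripped
#'   through this table; pathways travel in GMT form).
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = "",
                         comment.char = "#")
  structure(list(genes = g, pathways = list(), paralog_families = list()),
            class = "gene_catalog")
}

#' Write a JSON manifest
#' @param x list to serialise (seed, design, file inventory, ...).
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
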