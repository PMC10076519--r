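#' Read and write GMT gene-set files
#'
#' GMT is one set per line: name, description, then tab-separated gene ids.
#' Duplicate ids within a set are dropped (with a message giving the count);
#' a line with fewer than three fields is an error naming the line number.
#'
#' @param path file path.
#' @return named list of gene-id character vectors, with the descriptions in
#'   attribute \code{"descriptions"}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f) | seq_along(f) <= 2]
    if (length(f) < 3) {
      stop("read_gmt: line ", i, " has fewer than 3 fields")
    }
    genes <- f[-(1:2)]
    n_dup <- length(genes) - length(unique(genes))
    if (n_dup > 0) {
      message("read_gmt: set '", f[1], "': dropped ", n_dup, " duplicate ids")
    }
    sets[[f[1]]] <- unique(genes)
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else {
      "na"
    }
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' Tab-separated, first column \code{gene}, header row of sample ids. Values
#' are written in full precision (17 significant digits) so a write/read
#' cycle is an identity to floating-point resolution.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop("read_expression_matrix: ragged row at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1], ")")
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop("read_expression_matrix: first column must be named 'gene'")
  }
  if (anyDuplicated(df$gene)) {
    stop("read_expression_matrix: duplicate gene ids: ",
         paste(utils::head(df$gene[duplicated(df$gene)], 5), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("read_expression_matrix: duplicate sample ids")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_expression_matrix: non-numeric values")
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression_matrix
#' @param expr genes x samples numeric matrix with dimnames.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr),
                   signif(expr, 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked signature as a two-column TSV in rank order
#'
#' @param sig a ranked signature data.frame.
#' @param path file path.
#' @export
write_ranked_signature <- function(sig, path) {
  utils::write.table(sig[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reference compendium to disk
#'
#' One ranked-score TSV per cell line (genes x perturbagens, values are the
#' signature scores) plus a metadata CSV (\code{perturbagen_id},
#' \code{cell_line}, \code{class}).
#'
#' @param compendium a compendium list (\code{signatures}, \code{meta}).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- compendium$meta
  paths <- character(0)
  for (cl in unique(meta$cell_line)) {
    perts <- meta$perturbagen_id[meta$cell_line == cl]
    first <- compendium$signatures[[paste(perts[1], cl, sep = "|")]]
    genes <- sort(first$gene)
    cols <- lapply(perts, function(p) {
      s <- compendium$signatures[[paste(p, cl, sep = "|")]]
      s$score[match(genes, s$gene)]
    })
    df <- data.frame(gene = genes, stats::setNames(cols, perts),
                     check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(dir, paste0("compendium_", cl, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  meta_path <- file.path(dir, "compendium_meta.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(paths, meta_path))
}

#' Read a reference compendium written by \code{\link{write_compendium}}
#'
#' @param dir directory holding per-cell-line TSVs and the metadata CSV.
#' @return a compendium list (\code{signatures}, \code{meta}).
#' @export
read_compendium <- function(dir) {
  meta_path <- file.path(dir, "compendium_meta.csv")
  if (!file.exists(meta_path)) {
    stop("read_compendium: no compendium_meta.csv under ", dir)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  tabs <- lapply(stats::setNames(nm = unique(meta$cell_line)), function(cl) {
    utils::read.delim(file.path(dir, paste0("compendium_", cl, ".tsv")),
                      check.names = FALSE, stringsAsFactors = FALSE)
  })
  sigs <- list()
  for (i in seq_len(nrow(meta))) {  # meta row order = writer order
    df <- tabs[[meta$cell_line[i]]]
    score <- df[[meta$perturbagen_id[i]]]
    ord <- order(-score, df$gene)
    sigs[[paste(meta$perturbagen_id[i], meta$cell_line[i], sep = "|")]] <-
      data.frame(gene = df$gene[ord], score = score[ord],
                 stringsAsFactors = FALSE)
  }
  structure(list(signatures = sigs, meta = meta), class = "compendium")
}
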