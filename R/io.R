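#' Read and write the pipeline's tab-separated formats
#'
#' All on-disk formats are plain TSV for inspectability. Expression files
#' have probes as rows and a header of sample ids; label, probe-map, dosage,
#' SNP-metadata, phenotype and gene-boundary files are simple column tables.
#' Readers validate their schema and report offending line/column on error;
#' writers round-trip losslessly within float text precision.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param ds an [expression_dataset()]; written as three files with suffixes
#'   `_expr.tsv`, `_labels.tsv`, `_probemap.tsv` appended to `path`.
#' @export
write_expression <- function(ds, path) {
  expr <- data.frame(probe_id = ds$probe_ids, ds$abundance,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, paste0(path, "_expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = ds$sample_ids,
                                group = unname(ds$group_labels)),
                     paste0(path, "_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probe_id = names(ds$probe_to_gene),
                                gene = unname(ds$probe_to_gene)),
                     paste0(path, "_probemap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_expression <- function(path) {
  expr <- utils::read.delim(paste0(path, "_expr.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(expr)[1L] != "probe_id")
    stop(path, "_expr.tsv: first column must be probe_id", call. = FALSE)
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(mat) <- expr$probe_id
  labels <- utils::read.delim(paste0(path, "_labels.tsv"),
                              stringsAsFactors = FALSE)
  pm <- utils::read.delim(paste0(path, "_probemap.tsv"),
                          stringsAsFactors = FALSE)
  if (!identical(sort(labels$sample_id), sort(colnames(mat))))
    stop(path, "_labels.tsv: sample ids do not match expression header",
         call. = FALSE)
  expression_dataset(mat,
                     labels$group[match(colnames(mat), labels$sample_id)],
                     stats::setNames(pm$gene, pm$probe_id))
}

#' @rdname io
#' @param collection a [gene_set_collection()]; GMT lines are
#'   `name<TAB>description<TAB>gene...`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @param universe background gene list for the collection read from GMT;
#'   defaults to the union of all sets.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(path, " line ", i, ": GMT needs name, description and >= 1 gene",
           call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(path, " line ", i, ": duplicate genes in set '", f[1L],
              "' deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' @rdname io
#' @param network an igraph object; SIF lines are
#'   `geneA<TAB>interaction<TAB>geneB`.
#' @param relation interaction type written in the middle column.
#' @export
write_sif <- function(network, path, relation = "pp") {
  el <- igraph::as_edgelist(network, names = TRUE)
  writeLines(paste(el[, 1L], relation, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' @rdname io
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(!nf %in% c(2L, 3L)))
    stop(path, " line ", which(!nf %in% c(2L, 3L))[1L],
         ": expected 2-column edge list or 3-column SIF", call. = FALSE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, function(f) f[[length(f)]], character(1))
  g <- igraph::graph_from_data_frame(data.frame(from, to), directed = FALSE)
  igraph::simplify(g)
}

#' @rdname io
#' @param cohort a [genotype_cohort()]; written as `_dosage.tsv`,
#'   `_snps.tsv` and `_pheno.tsv` suffixed files.
#' @export
write_cohort <- function(cohort, path) {
  dos <- data.frame(sample_id = rownames(cohort$dosage), cohort$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(dos, paste0(path, "_dosage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$snp_meta, paste0(path, "_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$pheno, paste0(path, "_pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  dos_df <- utils::read.delim(paste0(path, "_dosage.tsv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  if (names(dos_df)[1L] != "sample_id")
    stop(path, "_dosage.tsv: first column must be sample_id", call. = FALSE)
  mat <- as.matrix(dos_df[, -1L, drop = FALSE])
  bad <- which(!(mat %in% c(0, 1, 2) | is.na(mat)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(path, "_dosage.tsv line ", bad[1L, 1L] + 1L, ", column '",
         colnames(mat)[bad[1L, 2L]], "': dosage value '",
         mat[bad[1L, , drop = FALSE]], "' is not 0, 1, 2 or NA",
         call. = FALSE)
  rownames(mat) <- dos_df$sample_id
  meta <- utils::read.delim(paste0(path, "_snps.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  pheno <- utils::read.delim(paste0(path, "_pheno.tsv"),
                             stringsAsFactors = FALSE)
  genotype_cohort(mat, meta, pheno)
}

#' @rdname io
#' @export
read_boundaries <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(b)))
    stop(path, ": boundaries need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad <- which(b$start > b$end)
  if (length(bad))
    stop(path, " line ", bad[1L] + 1L, ": start > end", call. = FALSE)
  b
}

#' @rdname io
#' @param x a data frame of results.
#' @export
write_results <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
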