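#' Read a GMT gene-set file
#'
#' Tab-separated lines `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param file Path to the GMT file.
#' @return Named list (by term id) of lists with `id`, `name`, `genes`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", f[1L])
    genes <- unique(f[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    list(id = f[1L], name = f[2L], genes = genes)
  })
  setNames(terms, vapply(terms, `[[`, character(1L), "id"))
}

#' Assemble an annotation catalog
#'
#' Bundles term -> gene-set annotations, an optional category label per term
#' (e.g. GO namespace or KEGG) and a background gene universe. Annotated
#' genes outside the background are trimmed (the catalog invariant is that
#' every term's gene set is contained in the background); terms left empty
#' are dropped with a warning.
#'
#' @param terms Either the result of [read_gmt()] or a named list of
#'   character gene vectors.
#' @param background Character vector of background genes; defaults to the
#'   union of all term genes.
#' @param categories Optional named character vector mapping term id ->
#'   category label; unlisted terms get category `"ALL"`.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, background = NULL, categories = NULL) {
  if (!length(terms)) stop("no annotation terms supplied")
  if (is.character(terms[[1L]])) {
    terms <- lapply(seq_along(terms), function(i) {
      list(id = names(terms)[i], name = names(terms)[i],
           genes = unique(terms[[i]]))
    })
    terms <- setNames(terms, vapply(terms, `[[`, character(1L), "id"))
  }
  if (is.null(background)) {
    background <- unique(unlist(lapply(terms, `[[`, "genes"),
                                use.names = FALSE))
  }
  background <- unique(as.character(background))
  if (!length(background)) stop("annotation background is empty")
  terms <- lapply(terms, function(tm) {
    tm$genes <- intersect(tm$genes, background)
    tm$category <- if (!is.null(categories) && tm$id %in% names(categories)) {
      unname(categories[tm$id])
    } else "ALL"
    tm
  })
  empty <- vapply(terms, function(tm) length(tm$genes) == 0L, logical(1L))
  if (any(empty)) {
    warning(sum(empty), " term(s) with no background genes dropped")
    terms <- terms[!empty]
  }
  if (!length(terms)) stop("no usable annotation terms after trimming")
  structure(list(terms = terms, background = background),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$terms), "terms,",
      length(x$background), "background genes\n")
  invisible(x)
}

enrich_empty_table <- function() {
  data.frame(Category = character(0), Term = character(0),
             term_id = character(0), Count = integer(0),
             Percentage = numeric(0), PValue = numeric(0),
             Genes = character(0), List.Total = integer(0),
             Pop.Hits = integer(0), Pop.Total = integer(0),
             Fold.Enrichment = numeric(0), Bonferroni = numeric(0),
             Benjamini = numeric(0), FDR = numeric(0),
             stringsAsFactors = FALSE)
}

# upper-tail hypergeometric: P(X >= k) with k successes observed among n
# draws, K annotated genes in a background of N
hyper_tail <- function(k, K, N, n) {
  if (k <= 0L) return(1)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of a gene list against an annotation catalog
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the overlap
#' between the query list and every annotated term, with an optional EASE
#' variant that decrements the overlap by one before testing (more
#' conservative; the convention of the DAVID web tool's "modified" p-value).
#' Multiple-testing corrections (Bonferroni, Benjamini-Hochberg, and a
#' Benjamini-Yekutieli column labelled FDR) are applied within each
#' annotation category, and the per-category totals (`List.Total`,
#' `Pop.Total`) count genes annotated to at least one term of that
#' category.
#'
#' @param query Character vector of candidate gene ids (deduplicated;
#'   entries outside the catalog background are dropped with a warning).
#' @param catalog An [annotation_catalog()].
#' @param test `"fisher"` (default) or `"ease"`.
#' @return `data.frame` with one row per term with overlap count >= 1,
#'   sorted by ascending p-value: columns `Category`, `Term`, `Count`,
#'   `Percentage`, `PValue`, `Genes`, `List.Total`, `Pop.Hits`,
#'   `Pop.Total`, `Fold.Enrichment`, `Bonferroni`, `Benjamini`, `FDR`.
#' @export
enrich <- function(query, catalog, test = c("fisher", "ease")) {
  test <- match.arg(test)
  stopifnot(inherits(catalog, "annotation_catalog"))
  query <- unique(as.character(query))
  if (!length(query)) stop("query gene list is empty")
  mapped <- intersect(query, catalog$background)
  if (length(mapped) < length(query)) {
    warning(length(query) - length(mapped),
            " query gene(s) outside the background dropped")
  }
  if (!length(mapped)) stop("no query genes map into the background")

  cats <- vapply(catalog$terms, `[[`, character(1L), "category")
  rows <- list()
  for (cc in unique(cats)) {
    tms <- catalog$terms[cats == cc]
    cat_genes <- unique(unlist(lapply(tms, `[[`, "genes"), use.names = FALSE))
    list_total <- length(intersect(mapped, cat_genes))
    pop_total <- length(cat_genes)
    for (tm in tms) {
      ov <- intersect(mapped, tm$genes)
      k <- length(ov)
      if (k < 1L) next
      K <- length(tm$genes)
      kk <- if (test == "ease") k - 1L else k
      p <- hyper_tail(kk, K, pop_total, list_total)
      rows[[length(rows) + 1L]] <- data.frame(
        Category = cc, Term = tm$name, term_id = tm$id,
        Count = k,
        Percentage = k / length(mapped),
        PValue = p,
        Genes = paste(sort_ids(ov), collapse = ", "),
        List.Total = list_total,
        Pop.Hits = K,
        Pop.Total = pop_total,
        Fold.Enrichment = (k / list_total) / (K / pop_total),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(enrich_empty_table())
  out <- do.call(rbind, rows)
  out$Bonferroni <- NA_real_
  out$Benjamini <- NA_real_
  out$FDR <- NA_real_
  for (cc in unique(out$Category)) {
    i <- out$Category == cc
    out$Bonferroni[i] <- p.adjust(out$PValue[i], method = "bonferroni")
    out$Benjamini[i] <- p.adjust(out$PValue[i], method = "BH")
    out$FDR[i] <- p.adjust(out$PValue[i], method = "BY")
  }
  o <- order(out$PValue, out$term_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' Emits the standard functional-annotation column set: Category, Term,
#' Count, Percentage, PValue, Genes, List Total, Pop Hits, Pop Total,
#' Fold Enrichment, Bonferroni, Benjamini, FDR.
#'
#' @param enrichment Result of [enrich()].
#' @param file Output path.
#' @export
write_enrichment <- function(enrichment, file) {
  cols <- c("Category", "Term", "Count", "Percentage", "PValue", "Genes",
            "List.Total", "Pop.Hits", "Pop.Total", "Fold.Enrichment",
            "Bonferroni", "Benjamini", "FDR")
  df <- enrichment[, cols, drop = FALSE]
  header <- c("Category", "Term", "Count", "Percentage", "PValue", "Genes",
              "List Total", "Pop Hits", "Pop Total", "Fold Enrichment",
              "Bonferroni", "Benjamini", "FDR")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
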