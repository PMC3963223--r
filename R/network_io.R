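#' Parse a STRING-style scored edge list
#'
#' Reads a plain-text interaction table in the dialect of STRING's
#' `protein.links` exports: whitespace- or tab-separated rows of
#' `id_a id_b combined_score`, with an optional header line and `#` comment
#' lines. Scores are integer combined scores on the 0--1000 scale; fractional
#' scores are accepted and rounded half up. Rows with score 0 are non-edges
#' and dropped, as are self-interactions and rows with fewer than three
#' fields (both reported). A score outside \[0, 1000\] is an error naming the
#' offending line.
#'
#' @param file Path to the edge-list file, or a connection.
#' @param quiet Suppress progress/drop-count messages.
#' @return A `data.frame` with columns `protein_a`, `protein_b` (character)
#'   and `score` (integer in 1..1000), one row per retained interaction.
#'   Reversed duplicates are retained here and collapsed by
#'   [build_network()].
#' @seealso [build_network()], [write_edge_list()]
#' @export
parse_edge_list <- function(file, quiet = FALSE) {
  lines <- if (inherits(file, "connection")) {
    readLines(file, warn = FALSE)
  } else {
    if (!is.character(file) || length(file) != 1L || !file.exists(file)) {
      stop("cannot read edge list: ", paste(file, collapse = ", "))
    }
    readLines(file, warn = FALSE)
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  # header heuristic: first row whose third field is non-numeric
  f1 <- fields[[1L]]
  if (nf[1L] < 3L || is.na(suppressWarnings(as.numeric(f1[3L])))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    nf <- nf[-1L]
    if (!length(fields)) return(empty)
  }

  malformed <- nf < 3L
  a <- b <- rep(NA_character_, length(fields))
  raw <- rep(NA_character_, length(fields))
  ok <- which(!malformed)
  a[ok] <- vapply(fields[ok], `[`, character(1L), 1L)
  b[ok] <- vapply(fields[ok], `[`, character(1L), 2L)
  raw[ok] <- vapply(fields[ok], `[`, character(1L), 3L)
  score_num <- suppressWarnings(as.numeric(raw))
  malformed <- malformed | (!malformed & is.na(score_num))

  bad <- !malformed & (score_num < 0 | score_num > 1000)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("combined score out of [0, 1000] (", score_num[i], ") on line ",
         lineno[i])
  }

  score <- as.integer(round_half_up(score_num))
  selfloop <- !malformed & a == b
  zero <- !malformed & !selfloop & score <= 0L
  drop <- malformed | selfloop | zero
  if (any(malformed)) {
    sp_message("parse_edge_list: dropped ", sum(malformed),
               " malformed row(s) (fewer than 3 fields or non-numeric score)",
               quiet = quiet)
  }
  if (any(selfloop)) {
    sp_message("parse_edge_list: dropped ", sum(selfloop),
               " self-interaction row(s)", quiet = quiet)
  }
  if (any(zero)) {
    sp_message("parse_edge_list: dropped ", sum(zero),
               " zero-score row(s) (non-edges)", quiet = quiet)
  }
  data.frame(protein_a = a[!drop], protein_b = b[!drop],
             score = score[!drop], stringsAsFactors = FALSE)
}

#' Build a weighted protein-protein interaction network
#'
#' Constructs the undirected weighted network used throughout the pipeline:
#' every interaction contributes its two endpoints as nodes and one edge
#' whose distance-like weight is `1000 - score`, so high-confidence
#' interactions are short. Duplicate rows for the same unordered pair
#' collapse to a single edge; conflicting duplicate scores resolve to the
#' maximum (strongest evidence) with a warning.
#'
#' @param interactions A `data.frame` as returned by [parse_edge_list()]
#'   (columns `protein_a`, `protein_b`, `score`).
#' @return An object of class `ppi_network`: a list with `nodes` (character,
#'   radix-sorted), parallel edge vectors `from`/`to` (integer node indices,
#'   `from < to`), `score` and `weight` (integers, `score + weight == 1000`).
#' @examples
#' net <- build_network(data.frame(protein_a = "A", protein_b = "B",
#'                                 score = 990L))
#' net$weight # 10
#' @export
build_network <- function(interactions) {
  stopifnot(is.data.frame(interactions),
            all(c("protein_a", "protein_b", "score") %in% names(interactions)))
  a <- as.character(interactions$protein_a)
  b <- as.character(interactions$protein_b)
  s <- as.integer(interactions$score)
  if (any(is.na(s)) || any(s < 1L) || any(s > 1000L)) {
    stop("interaction scores must be integers in (0, 1000]")
  }
  if (any(a == b)) stop("self-interactions are not allowed")

  nodes <- sort_ids(unique(c(a, b)))
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  from <- pmin(ia, ib)
  to <- pmax(ia, ib)
  key <- (as.numeric(from) - 1) * length(nodes) + as.numeric(to)
  # keep the maximum score per unordered pair
  o <- order(key, -s)
  first <- !duplicated(key[o])
  dup_conflict <- anyDuplicated(key) &&
    any(tapply(s, key, function(x) length(unique(x)) > 1L))
  if (dup_conflict) {
    warning("conflicting duplicate scores for some pairs; keeping the maximum")
  }
  sel <- o[first]
  structure(list(nodes = nodes,
                 from = from[sel],
                 to = to[sel],
                 score = s[sel],
                 weight = 1000L - s[sel]),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", length(x$from), "edges\n")
  if (length(x$from)) {
    cat("  score range:", min(x$score), "-", max(x$score),
        " (weight ", min(x$weight), "-", max(x$weight), ")\n", sep = "")
  }
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param network A `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) length(network$from)

#' Write a network back to edge-list form
#'
#' Emits `id_a<TAB>id_b<TAB>score` rows (no header). Re-parsing the file
#' through [parse_edge_list()] + [build_network()] reconstructs an identical
#' network.
#'
#' @param network A `ppi_network`.
#' @param file Output path.
#' @export
write_edge_list <- function(network, file) {
  df <- data.frame(a = network$nodes[network$from],
                   b = network$nodes[network$to],
                   score = network$score)
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a seed gene list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#'
#' @param file Path to the list.
#' @return Character vector of identifiers in file order (duplicates kept;
#'   [resolve_seeds()] deduplicates).
#' @export
read_seed_list <- function(file) {
  x <- readLines(file, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Read a two-column identifier mapping file
#'
#' TSV/whitespace `input_id network_id`; used to translate seed symbols into
#' the network's identifier namespace. Identifiers are otherwise treated as
#' opaque strings.
#'
#' @param file Path to the mapping file.
#' @return Named character vector: `names` are input ids, values network ids.
#' @export
read_id_map <- function(file) {
  df <- utils::read.table(file, header = FALSE, colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("id map must have two columns")
  setNames(df[[2L]], df[[1L]])
}

#' Resolve a seed gene list against a network
#'
#' Deduplicates the requested identifiers (first occurrence wins), optionally
#' translates them through an id map, and partitions them into those present
#' as network nodes (`mapped`) and the rest (`unmapped`, logged by name). The
#' pipeline proceeds with mapped seeds only; an empty mapped set is a fatal
#' configuration error.
#'
#' @param gene_list Character vector of requested seed identifiers.
#' @param network A `ppi_network`.
#' @param id_map Optional named character vector from [read_id_map()].
#' @param quiet Suppress messages.
#' @return An object of class `seed_gene_set`: list with `requested`,
#'   `mapped` (network-namespace ids) and `unmapped` (input-namespace ids).
#' @export
resolve_seeds <- function(gene_list, network, id_map = NULL, quiet = FALSE) {
  if (!length(gene_list)) stop("seed gene list is empty")
  requested <- unique(as.character(gene_list))
  target <- requested
  if (!is.null(id_map)) {
    hit <- requested %in% names(id_map)
    target[hit] <- unname(id_map[requested[hit]])
  }
  present <- target %in% network$nodes
  mapped <- unique(target[present])
  unmapped <- requested[!present]
  if (!length(mapped)) {
    stop("none of the ", length(requested),
         " requested seed genes map to network nodes")
  }
  if (length(unmapped)) {
    sp_message("resolve_seeds: ", length(unmapped),
               " unmapped seed gene(s) dropped: ",
               paste(head(unmapped, 20L), collapse = ", "),
               if (length(unmapped) > 20L) ", ...", quiet = quiet)
  }
  structure(list(requested = requested, mapped = mapped, unmapped = unmapped),
            class = "seed_gene_set")
}

#' @export
print.seed_gene_set <- function(x, ...) {
  cat("seed_gene_set:", length(x$requested), "requested,",
      length(x$mapped), "mapped,", length(x$unmapped), "unmapped\n")
  invisible(x)
}

# coerce character vectors into a seed set resolved against `network`
as_seed_set <- function(seeds, network) {
  if (inherits(seeds, "seed_gene_set")) return(seeds)
  resolve_seeds(as.character(seeds), network, quiet = TRUE)
}
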