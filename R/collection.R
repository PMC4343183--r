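#' Construct a pathway collection
#'
#' A pathway collection is the unit of clustering: a tibble with one row per
#' pathway and columns `pathway_id` (unique), `source`, `name` and `genes`
#' (a list-column of character vectors of gene symbols). The gene universe is
#' the union of all member gene sets.
#'
#' @param pathways A data frame with columns `pathway_id`, `source`, `name`,
#'   `genes`. Gene sets must be non-empty; duplicate symbols within a pathway
#'   are collapsed.
#' @param normalize Upper-case and whitespace-strip gene symbols?
#'
#' @return A tibble of class `pathway_collection`.
#' @export
#' @examples
#' pathway_collection(tibble::tibble(
#'   pathway_id = c("P1", "P2"),
#'   source = "KEGG",
#'   name = c("Oocyte meiosis", "Cell cycle"),
#'   genes = list(c("AURKA", "BUB1"), c("BUB1", "CDC20"))
#' ))
pathway_collection <- function(pathways, normalize = FALSE) {
  pathways <- as_tibble(pathways)
  required <- c("pathway_id", "source", "name", "genes")
  missing <- setdiff(required, names(pathways))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  pathways <- pathways[required]
  pathways$pathway_id <- as.character(pathways$pathway_id)
  pathways$source <- as.character(pathways$source)
  pathways$name <- as.character(pathways$name)
  if (anyDuplicated(pathways$pathway_id)) {
    dup <- unique(pathways$pathway_id[duplicated(pathways$pathway_id)])
    abort(paste0("duplicate pathway id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  pathways$genes <- lapply(pathways$genes, function(g) {
    g <- as.character(g)
    if (normalize) g <- toupper(trimws(g))
    unique(g[!is.na(g) & nzchar(g)])
  })
  if (nrow(pathways) > 0 && any(lengths(pathways$genes) == 0)) {
    abort("every pathway must have at least one gene")
  }
  class(pathways) <- c("pathway_collection", class(as_tibble(tibble())))
  pathways
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf(
    "# A pathway collection: %d pathways, %d sources, %d genes\n",
    nrow(x), length(unique(x$source)), length(gene_universe(x))
  ))
  NextMethod()
}

# tibble verbs strip the subclass; re-tag after internal manipulation
as_collection <- function(df) {
  class(df) <- c("pathway_collection", class(as_tibble(tibble())))
  df
}

#' Gene universe of a collection
#'
#' All genes appearing in at least one pathway.
#'
#' @param collection A [pathway_collection()].
#' @return Character vector of gene symbols (sorted, unique).
#' @export
gene_universe <- function(collection) {
  sort(unique(unlist(collection$genes, use.names = FALSE)))
}

#' Read gene sets from a GMT file
#'
#' One gene set per tab-separated line: id, description, then gene symbols.
#' The description field is parsed as `"source|name"`; a description without
#' the `|` separator yields `source = "unknown"`.
#'
#' @param path Path to a GMT file.
#' @param normalize Upper-case and whitespace-strip gene symbols?
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, normalize = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(pathway_collection(tibble(
      pathway_id = character(), source = character(),
      name = character(), genes = list()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", bad[1]))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  has_sep <- grepl("|", desc, fixed = TRUE)
  source <- ifelse(has_sep, sub("\\|.*$", "", desc), "unknown")
  name <- ifelse(has_sep, sub("^[^|]*\\|", "", desc), desc)
  pathway_collection(
    tibble(
      pathway_id = vapply(fields, `[[`, character(1), 1),
      source = source,
      name = name,
      genes = lapply(fields, function(f) f[-(1:2)])
    ),
    normalize = normalize
  )
}

#' Write a collection to a GMT file
#'
#' Inverse of [read_gmt()]: the round trip reproduces ids, sources, names and
#' gene sets exactly. Tabs inside names would break the format and are
#' replaced by spaces with a warning.
#'
#' @param collection A [pathway_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  name <- collection$name
  if (any(grepl("\t", name, fixed = TRUE))) {
    warn("tab character(s) in pathway names replaced by spaces")
    name <- gsub("\t", " ", name, fixed = TRUE)
  }
  lines <- character(nrow(collection))
  if (nrow(collection) > 0) {
    lines <- paste(
      collection$pathway_id,
      paste(collection$source, name, sep = "|"),
      vapply(collection$genes, paste, character(1), collapse = "\t"),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-source summary statistics
#'
#' One row per source: number of pathways, size of the source's gene union,
#' and the mean and standard deviation of pathway sizes.
#'
#' @param collection A [pathway_collection()].
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1) for the size standard deviation.
#' @return A tibble with columns `source`, `n_pathways`, `n_genes`,
#'   `mean_size`, `sd_size`, sorted by decreasing `n_genes`.
#' @export
source_summary <- function(collection, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sizes <- lengths(collection$genes)
  tibble(source = collection$source, size = sizes, genes = collection$genes) %>%
    group_by(.data$source) %>%
    summarise(
      n_pathways = n(),
      n_genes = length(unique(unlist(.data$genes))),
      mean_size = mean(.data$size),
      sd_size = if (sd_type == "population") {
        sqrt(mean((.data$size - mean(.data$size))^2))
      } else {
        if (n() > 1) sd(.data$size) else 0
      },
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$n_genes))
}

#' Cumulative gene coverage over sources
#'
#' Adds sources one at a time and records the cumulative number of distinct
#' genes, showing how quickly extra sources stop contributing new genes.
#'
#' @param collection A [pathway_collection()].
#' @param source_order Character vector of source labels; defaults to
#'   descending per-source gene count. Must be a subset of sources present.
#' @return A tibble with columns `source`, `n_sources`, `cumulative_genes`
#'   (non-decreasing; the final value is the universe size when all sources
#'   are listed).
#' @export
coverage_curve <- function(collection, source_order = NULL) {
  present <- unique(collection$source)
  if (is.null(source_order)) {
    source_order <- source_summary(collection)$source
  }
  unknown <- setdiff(source_order, present)
  if (length(unknown) > 0) {
    abort(paste0("unknown source(s): ", paste(unknown, collapse = ", ")))
  }
  seen <- character(0)
  cum <- integer(length(source_order))
  for (k in seq_along(source_order)) {
    seen <- union(seen, unlist(collection$genes[collection$source == source_order[k]]))
    cum[k] <- length(seen)
  }
  tibble(source = source_order, n_sources = seq_along(source_order), cumulative_genes = cum)
}

#' Binary pathway-by-gene membership matrix
#'
#' @param collection A [pathway_collection()].
#' @return An integer matrix with one row per pathway (rownames = pathway
#'   ids), one column per universe gene, cell 1 iff the gene belongs to the
#'   pathway. Row sums equal pathway sizes.
#' @export
membership_matrix <- function(collection) {
  genes <- gene_universe(collection)
  m <- matrix(
    0L, nrow = nrow(collection), ncol = length(genes),
    dimnames = list(collection$pathway_id, genes)
  )
  for (i in seq_len(nrow(collection))) {
    m[i, collection$genes[[i]]] <- 1L
  }
  m
}
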