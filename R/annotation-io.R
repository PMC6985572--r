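# gene2go annotation parsing, label lists and feature tables.

#' NCBI taxonomy identifiers for the eight supported species
#'
#' Named lookup from species name to NCBI tax_id. Budding yeast gene2go
#' releases have used both the strain identifier 559292 and the species
#' identifier 4932; both are listed.
#'
#' @format Named character vector.
#' @export
taxon_ids <- c(
  human = "9606", mouse = "10090", rat = "10116", fly = "7227",
  worm = "6239", zebrafish = "7955", arabidopsis = "3702",
  yeast = "559292", yeast_species = "4932"
)

#' Construct a per-gene annotation
#'
#' A gene's annotation is its deduplicated set of cellular-component terms
#' (the term cluster of size `n` from which the SDI is computed). Terms are
#' stored sorted so downstream results are order-stable.
#'
#' @param gene_id gene identifier string.
#' @param terms character vector of term identifiers; duplicates collapsed.
#' @return Object of class `gene_annotation` with fields `gene_id`, `terms`,
#'   `n`.
#' @export
gene_annotation <- function(gene_id, terms) {
  terms <- sort(unique(as.character(terms)))
  if (!length(terms)) stop("gene_annotation requires at least one term")
  structure(list(gene_id = as.character(gene_id), terms = terms,
                 n = length(terms)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %s: %d term(s)\n", x$gene_id, x$n))
  invisible(x)
}

#' Parse a gene2go-format annotation table
#'
#' Reads NCBI gene2go tab-separated files (columns `tax_id`, `GeneID`,
#' `GO_ID`, `Evidence`, `Qualifier`, `GO_term`, `PubMed`, `Category`; one
#' leading `#` header line; gzip read transparently) into one
#' [gene_annotation()] per gene of the requested taxon.
#'
#' Rows are kept only when the term — after `alt_id` resolution — is a member
#' of `dag`, which doubles as the namespace filter; the `Category` column,
#' when informative, is used as a fast pre-filter. Duplicate (gene, term)
#' pairs arising from multiple evidence lines are collapsed: a repeated term
#' counts once.
#'
#' @param path path to a gene2go-format file.
#' @param taxon NCBI tax_id (string or number); see [taxon_ids].
#' @param dag companion [ontology_dag()] (cellular component).
#' @param exclude_iea drop rows with evidence code `IEA` (default `FALSE`,
#'   i.e. all evidence codes included).
#' @param exclude_not drop rows whose Qualifier contains `NOT` (default
#'   `TRUE`: a NOT qualifier asserts *non*-localization).
#' @return Named list of [gene_annotation()] objects, sorted by gene id.
#'   Empty (with a warning) when no gene of the taxon survives.
#' @export
parse_gene2go <- function(path, taxon, dag, exclude_iea = FALSE,
                          exclude_not = TRUE) {
  if (!file.exists(path)) stop("cannot read gene2go file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 8L
  if (any(bad)) {
    message(sum(bad), " malformed row(s) skipped")
    parts <- parts[!bad]
  }
  if (!length(parts)) {
    warning("no annotation rows found")
    return(stats::setNames(list(), character()))
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  tax <- col(1); gene <- col(2); go <- col(3); evidence <- col(4)
  qualifier <- col(5); category <- col(8)

  keep <- tax == as.character(taxon)
  if (exclude_iea) keep <- keep & evidence != "IEA"
  if (exclude_not) keep <- keep & !grepl("\\bNOT\\b", qualifier)
  # Category pre-filter: only trusted when the column is informative;
  # DAG membership below is the authoritative namespace filter.
  informative <- nzchar(category) & category != "-"
  keep <- keep & (!informative | category == "Component")

  gene <- gene[keep]; go <- go[keep]
  resolved <- vapply(go, function(t) {
    r <- resolve_term(dag, t)
    if (is.na(r)) NA_character_ else r
  }, character(1), USE.NAMES = FALSE)
  unknown <- is.na(resolved)
  if (any(unknown)) {
    warning(sum(unknown), " annotation row(s) referencing terms absent from ",
            "the ontology (obsolete or out-of-namespace) dropped")
  }
  gene <- gene[!unknown]; resolved <- resolved[!unknown]
  if (!length(gene)) {
    warning("no genes with surviving annotations for taxon ", taxon)
    return(stats::setNames(list(), character()))
  }
  by_gene <- split(resolved, gene)
  by_gene <- by_gene[order(names(by_gene))]
  out <- lapply(names(by_gene), function(g) gene_annotation(g, by_gene[[g]]))
  stats::setNames(out, names(by_gene))
}

#' Read a one-gene-per-line label list
#'
#' @param path path to a plain text file, one gene identifier per line.
#' @param name label name (e.g. `"essential"`, `"drug_target"`); defaults to
#'   the file name without extension.
#' @return A [label_set()].
#' @export
read_label_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genes <- readLines(path, warn = FALSE)
  genes <- trimws(genes)
  label_set(name, genes[nzchar(genes)])
}

#' Construct a label set
#'
#' @param name label name.
#' @param positives character vector of positive gene identifiers.
#' @return Object of class `label_set` with fields `name`, `positives`.
#' @export
label_set <- function(name, positives) {
  positives <- unique(as.character(positives))
  if (!length(positives)) stop("label set '", name, "' is empty")
  structure(list(name = name, positives = positives), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %s: %d positive gene(s)\n", x$name,
              length(x$positives)))
  invisible(x)
}

#' Read a gene-level feature table
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' remaining columns hold numeric features (header row required).
#'
#' @param path path to a TSV file.
#' @return data frame with a character `gene_id` first column and numeric
#'   feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("feature table needs a gene column and >=1 feature")
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  for (j in seq(2L, ncol(df))) df[[j]] <- as.numeric(df[[j]])
  df
}
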