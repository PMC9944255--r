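#' Gene set categories recognized by the package
#'
#' Provenance tags used to classify signatures: mesenchymal EMT programs
#' (\code{EMT}), the epithelial pre-transition program (\code{EMT_EPI}),
#' ESTIMATE-style stroma and immune signatures, TGF-beta pathway sets, the
#' CAF (cancer-associated fibroblast) signature, and \code{OTHER}.
#'
#' @return Character vector of valid category labels.
#' @export
gene_set_categories <- function() {
  c("EMT", "EMT_EPI", "STROMA", "IMMUNE", "TGFB", "CAF", "OTHER")
}

#' Construct a gene set
#'
#' A named, ordered list of unique gene identifiers with a provenance
#' category. Identifiers are opaque, case-sensitive strings; no symbol
#' aliasing is performed. Duplicates are removed preserving first occurrence.
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene identifiers; de-duplicated keeping
#'   first occurrence.
#' @param category One of [gene_set_categories()].
#' @param allow_empty Internal escape used by [sentinel_expansion()] when no
#'   gene passes the cutoff; ordinary construction requires >= 1 gene.
#' @return A \code{GeneSet} object (list with \code{name}, \code{genes},
#'   \code{category}).
#' @export
gene_set <- function(name, genes, category = "OTHER", allow_empty = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("gene set name must be non-empty")
  category <- match.arg(category, gene_set_categories())
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L && !allow_empty) {
    stop("gene set '", name, "' has no genes")
  }
  structure(list(name = name, genes = genes, category = category),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s' [%s]: %d genes\n", x$name, x$category,
              length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 8L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

#' Construct a collection of gene sets
#'
#' @param sets List of [gene_set()] objects; names must be unique.
#' @return A \code{GeneSetCollection} (named list of \code{GeneSet}).
#' @export
gene_set_collection <- function(sets = list()) {
  stopifnot(is.list(sets))
  for (s in sets) {
    if (!inherits(s, "GeneSet")) stop("all elements must be GeneSet objects")
  }
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(sets, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-32s %-8s %d genes\n", s$name, s$category,
                length(s$genes)))
  }
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated, field 1 the set name,
#' field 2 a description (ignored unless it names a category written by
#' [write_gmt()]), remaining fields gene identifiers. Blank gene fields and
#' trailing tabs are skipped; trailing blank lines are ignored. Duplicate
#' genes within a line are de-duplicated preserving first occurrence.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # trailing blank lines are tolerated; interior blank lines are skipped too
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # drop trailing empty fields (trailing tabs)
    while (length(fields) && !nzchar(fields[length(fields)])) {
      fields <- fields[-length(fields)]
    }
    if (length(fields) < 3L) {
      stop("malformed GMT line ", line_no[i],
           ": expected >= 3 tab-separated fields, got ", length(fields))
    }
    desc <- fields[2]
    category <- if (desc %in% gene_set_categories()) desc else "OTHER"
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)], category = category)
    attr(sets[[i]], "description") <- desc
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' The description field carries the set's category so that a write/read
#' round trip preserves names, order, membership and category exactly.
#'
#' @param collection A [gene_set_collection()] (or single [gene_set()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "GeneSet")) {
    collection <- gene_set_collection(list(collection))
  }
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$category, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 3-gene CAF signature
#'
#' The compact cancer-associated fibroblast transcriptional signature:
#' collagen genes COL1A1, COL1A2 and COL3A1, originally obtained by
#' mutual-rank co-expression expansion around the CAF sentinel marker FAP
#' (see [sentinel_expansion()]).
#'
#' @return A [gene_set()] of 3 genes, category \code{CAF}.
#' @export
caf_signature <- function() {
  gene_set("CAF_SIGNATURE", c("COL1A1", "COL1A2", "COL3A1"),
           category = "CAF")
}

#' Names of the eight published EMT signatures
#'
#' The registry of EMT gene-signature names tracked by the package. Seven
#' measure the mesenchymal program; GENERIC_EMT_EPI_Tan_2014 captures the
#' epithelial pre-transition state and is expected to behave in the
#' opposite direction in stromal analyses.
#'
#' @return Character vector of 8 signature names.
#' @export
emt_signature_names <- function() {
  c("EMT_Carretero_2010", "IPRES_Hugo_2016", "PATHWAY_Carretero_2010",
    "EMT_STROMA_Wang_2018", "GENERIC_EMT_MES_Tan_2014", "HALLMARK_EMT",
    "PAN_EMT_Mak_2016", "GENERIC_EMT_EPI_Tan_2014")
}

#' Packaged signature registry
#'
#' Reads the registry GMT shipped with the package: the CAF signature with
#' its real membership, plus the 8 EMT signature names whose memberships
#' are copyrighted/curated elsewhere and must be supplied by the user
#' (placeholder gene token \code{USER_MUST_SUPPLY}; flagged via the
#' \code{user_must_supply} attribute on each affected set).
#'
#' @return A [gene_set_collection()] of 9 sets.
#' @export
signature_registry <- function() {
  path <- system.file("extdata", "signature_registry.gmt", package = "cafsig")
  coll <- read_gmt(path)
  for (nm in names(coll)) {
    attr(coll[[nm]], "user_must_supply") <-
      identical(coll[[nm]]$genes, "USER_MUST_SUPPLY")
  }
  coll
}
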