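#' Gene signatures and signature families
#'
#' Immune polarization subsets (Th1/Th2/Th17/iTreg for T helper cells, M1/M2
#' for macrophages) are each defined by a small set of cytokine and
#' lineage-defining transcription-factor genes. A `signature_family` bundles
#' the K >= 2 alternative subsets of one cell type; polarization among them
#' is modeled as a mutually exclusive process, so inference uses the
#' *exclusive* gene sets: each subset's genes minus any gene shared with
#' another subset of the same family.
#'
#' @name gene-panels
NULL

#' Canonicalize gene symbols
#'
#' Maps the two symbol dialects seen in expression exports onto one form:
#' `.` becomes `-` (R-style `HLA.DRA` vs `HLA-DRA`) and case is upper.
#'
#' @param x character vector of gene symbols
#' @return character vector of canonical symbols
#' @export
canonical_symbol <- function(x) {
  toupper(gsub(".", "-", as.character(x), fixed = TRUE))
}

#' Construct a gene signature
#'
#' @param name subset label, e.g. `"Th1"` or `"M2"`
#' @param genes character vector of gene symbols (canonicalized, must be
#'   nonempty and unique after canonicalization)
#' @param family family label, e.g. `"Thelper"`
#' @return a `gene_signature` object
#' @export
gene_signature <- function(name, genes, family = "other") {
  genes <- canonical_symbol(genes)
  if (length(genes) == 0L) {
    stop("signature '", name, "' has no genes", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("signature '", name, "' has duplicated symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, genes = genes, family = family),
            class = "gene_signature")
}

#' Construct a signature family
#'
#' @param label family label
#' @param subsets list of [gene_signature()] objects, K >= 2 for families
#'   meant for polarization inference (a single subset is allowed for plain
#'   marker collections)
#' @param reduce compute the mutually exclusive gene sets immediately?
#' @return a `signature_family` with elements `label`, `subsets` and (after
#'   reduction) `exclusive`, a named list of pairwise disjoint gene sets
#' @export
signature_family <- function(label, subsets, reduce = FALSE) {
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, `[[`, "", "name")
  }
  fam <- structure(list(label = label, subsets = subsets, exclusive = NULL),
                   class = "signature_family")
  if (reduce) fam <- reduce_to_exclusive(fam) else fam
}

#' @export
print.signature_family <- function(x, ...) {
  cat("signature family '", x$label, "' (K = ", length(x$subsets), ")\n",
      sep = "")
  for (s in x$subsets) {
    excl <- if (!is.null(x$exclusive)) {
      paste0(" | exclusive: ", paste(x$exclusive[[s$name]], collapse = " "))
    } else ""
    cat("  ", s$name, ": ", paste(s$genes, collapse = " "), excl, "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of subsets in a family
#' @param family a `signature_family`
#' @return integer K
#' @export
n_subsets <- function(family) length(family$subsets)

#' Reduce a signature family to mutually exclusive gene sets
#'
#' Each subset's exclusive set is its gene list minus every gene appearing
#' in any other subset of the same family. Inference treats polarization as
#' mutually exclusive, so shared lineage genes (e.g. CD4, present in all
#' four T-helper subsets) carry no discriminating information and are
#' removed.
#'
#' @param family a `signature_family` with K >= 2 subsets
#' @return the family with `exclusive` filled in
#' @export
reduce_to_exclusive <- function(family) {
  stopifnot(inherits(family, "signature_family"))
  if (n_subsets(family) < 2L) {
    stop("family '", family$label, "' needs >= 2 subsets to reduce",
         call. = FALSE)
  }
  gene_lists <- lapply(family$subsets, `[[`, "genes")
  excl <- lapply(seq_along(gene_lists), function(k) {
    others <- unique(unlist(gene_lists[-k], use.names = FALSE))
    setdiff(gene_lists[[k]], others)
  })
  names(excl) <- names(gene_lists)
  empty <- names(excl)[lengths(excl) == 0L]
  if (length(empty)) {
    stop("exclusive set empty after reduction for subset(s): ",
         paste(empty, collapse = ", "), " in family '", family$label, "'",
         call. = FALSE)
  }
  family$exclusive <- excl
  family
}

#' All genes of a family (union over subsets)
#' @param family a `signature_family`
#' @return character vector of canonical symbols
#' @export
family_genes <- function(family) {
  unique(unlist(lapply(family$subsets, `[[`, "genes"), use.names = FALSE))
}

#' Load a gene panel definition file
#'
#' The panel file is a YAML mapping `family -> subset -> [symbols]`. The
#' packaged default (`default_panel_path()`) encodes the full immune panel:
#' the T-helper (Th1/Th2/Th17/iTreg) and macrophage (M1/M2) polarization
#' families, the NK / T cell / macrophage infiltration marker sets, and the
#' functional-annotation gene sets used for clustering and PCA only.
#'
#' @param path path to a YAML panel file; defaults to the packaged panel
#' @return named list of `signature_family` objects
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse panel file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(raw) || is.null(names(raw))) {
    stop("panel file must be a mapping family -> subset -> [symbols]",
         call. = FALSE)
  }
  families <- lapply(names(raw), function(famname) {
    fam <- raw[[famname]]
    if (!is.list(fam) || is.null(names(fam))) {
      stop("family '", famname, "' must map subset names to gene lists",
           call. = FALSE)
    }
    subsets <- lapply(names(fam), function(sub) {
      genes <- unlist(fam[[sub]], use.names = FALSE)
      if (length(genes) == 0L) {
        stop("subset '", sub, "' of family '", famname,
             "' lists zero genes", call. = FALSE)
      }
      gene_signature(sub, genes, family = famname)
    })
    signature_family(famname, subsets)
  })
  names(families) <- names(raw)
  families
}

#' Path to the packaged default panel file
#' @return file path
#' @export
default_panel_path <- function() {
  system.file("extdata", "immune_panel.yaml", package = "immunopolar",
              mustWork = TRUE)
}

#' Write a panel to a YAML file
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p, f))` reproduces the
#' panel.
#'
#' @param panel named list of `signature_family` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  out <- lapply(panel, function(fam) lapply(fam$subsets, `[[`, "genes"))
  names(out) <- vapply(panel, `[[`, "", "label")
  yaml::write_yaml(out, path)
  invisible(path)
}

#' T-helper family with the revised Th2 signature
#'
#' The Th2 subset is replaced by `{CD4, IL4, IL5, IL10, GATA3}`: PPARG is
#' removed because it can repress IL4 transcription and so may mark
#' sensitivity to negative regulation rather than a type 2 bias, and IL6 is
#' removed with it. The other three subsets are unchanged (K stays 4).
#'
#' @param panel panel list to take the reference T-helper family from
#' @return a `signature_family` (not yet reduced)
#' @export
revised_th2_family <- function(panel = load_panel()) {
  fam <- panel[["Thelper"]]
  if (is.null(fam)) stop("panel has no 'Thelper' family", call. = FALSE)
  fam$subsets[["Th2"]] <- gene_signature(
    "Th2", c("CD4", "IL4", "IL5", "IL10", "GATA3"), family = fam$label)
  fam$exclusive <- NULL
  fam
}

#' Restrict a family to genes present in an expression matrix
#'
#' Genes absent from the matrix are dropped with a warning (platform gene
#' coverage varies); an error is raised only if a subset's exclusive set
#' would become empty.
#'
#' @param family a reduced `signature_family`
#' @param genes character vector of available gene symbols
#' @return the family with subsets and exclusive sets intersected with
#'   `genes`
#' @export
restrict_family <- function(family, genes) {
  genes <- canonical_symbol(genes)
  if (is.null(family$exclusive)) family <- reduce_to_exclusive(family)
  missing <- setdiff(family_genes(family), genes)
  if (length(missing)) {
    warning("dropping panel genes absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  family$subsets <- lapply(family$subsets, function(s) {
    s$genes <- intersect(s$genes, genes)
    s
  })
  family$exclusive <- lapply(family$exclusive, intersect, genes)
  empty <- names(family$exclusive)[lengths(family$exclusive) == 0L]
  if (length(empty)) {
    stop("no genes left in exclusive set of subset(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  family
}
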