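#' Read a genes-by-samples TPM expression table
#'
#' Expression tables are tab-separated with a header row of sample
#' identifiers and gene identifiers in the first column. Gene and sample
#' identifiers are treated as opaque, case-sensitive strings; no identifier
#' mapping is attempted. Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV (optionally gzipped) expression table.
#' @param tpm_check If `TRUE`, verify that every sample column sums to 1e6
#'   within a relative tolerance of 1e-6 and act per `tpm_action`.
#' @param tpm_action What to do when `tpm_check` fails: `"error"` rejects
#'   the file, `"renormalize"` rescales each column to sum to 1e6.
#'
#' @return A tibble with a `gene_id` character column followed by one
#'   numeric column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(tpm_normalize(
#'   tibble::tibble(gene_id = c("A", "B"), S1 = c(1, 3), S2 = c(2, 2))), tf)
#' read_expression(tf, tpm_check = TRUE)
read_expression <- function(path, tpm_check = FALSE,
                            tpm_action = c("error", "renormalize")) {
  tpm_action <- match.arg(tpm_action)
  # base strtod parsing is correctly rounded, keeping write/read round
  # trips bit-exact; gzip is handled transparently by file()
  tbl <- as_tibble(utils::read.delim(path, sep = "\t", quote = "",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE))
  if (ncol(tbl) < 2) {
    abort("expression table needs a gene column plus at least one sample")
  }
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  validate_expression(tbl)
  if (tpm_check && !is_tpm(tbl)) {
    if (tpm_action == "error") {
      abort("sample columns do not sum to 1e6 (TPM); use tpm_action = \"renormalize\" to rescale")
    }
    tbl <- tpm_normalize(tbl)
  }
  tbl
}

#' Write an expression table to TSV
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param path Output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  out <- expr
  # 17 significant digits make the decimal round-trip bit-exact
  out[-1] <- lapply(out[-1], function(x) sprintf("%.17g", x))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Reject duplicate identifiers and non-finite / negative values with
# coordinates; missing values are rejected, never imputed.
validate_expression <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort("expression table must be a data frame with a gene_id column")
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicate gene identifiers: ",
                 paste(head(dup_g, 5), collapse = ", ")))
  }
  smp <- setdiff(names(expr), "gene_id")
  dup_s <- unique(smp[duplicated(smp)])
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample identifiers: ", paste(dup_s, collapse = ", ")))
  }
  m <- expr_matrix(expr, .validate = FALSE)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-finite or negative expression values, e.g. gene ",
                 rownames(m)[bad[1, 1]], " sample ", colnames(m)[bad[1, 2]]))
  }
  invisible(expr)
}

#' Convert between the expression tibble and a numeric matrix
#'
#' @param expr Expression tibble.
#' @param .validate Run validation first.
#' @return `expr_matrix()`: a genes-by-samples numeric matrix with gene ids
#'   as rownames. `expr_tibble()`: the inverse.
#' @export
expr_matrix <- function(expr, .validate = TRUE) {
  if (.validate) validate_expression(expr)
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' @rdname expr_matrix
#' @param m Genes-by-samples numeric matrix with rownames.
#' @export
expr_tibble <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

#' Scale every sample column to transcripts per million
#'
#' Each sample column is rescaled to sum to 1e6. Idempotent.
#'
#' @param expr Expression tibble.
#' @return Rescaled expression tibble.
#' @export
tpm_normalize <- function(expr) {
  m <- expr_matrix(expr)
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(paste0("cannot TPM-normalize all-zero sample: ",
                 colnames(m)[which(cs == 0)[1]]))
  }
  expr_tibble(sweep(m, 2, cs / 1e6, "/"))
}

#' @rdname tpm_normalize
#' @param tol Relative tolerance on the 1e6 column sum.
#' @return `is_tpm()`: logical.
#' @export
is_tpm <- function(expr, tol = 1e-6) {
  cs <- colSums(expr_matrix(expr))
  all(abs(cs - 1e6) <= tol * 1e6)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one gene per field. Duplicate
#' genes within a set are an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description` and a `genes`
#'   list-column of character vectors. Empty files give zero rows.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(set = character(), description = character(),
                  genes = list()))
  }
  parsed <- imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 fields"))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      abort(paste0("GMT line ", i, " (", f[1], ") has duplicate genes"))
    }
    tibble(set = f[1], description = f[2], genes = list(genes))
  })
  out <- bind_rows(parsed)
  if (anyDuplicated(out$set)) abort("duplicate gene-set names in GMT")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A tibble as returned by [read_gmt()], or a named list of
#'   character vectors (descriptions default to the set name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_sets(sets)
  lines <- pmap(sets, function(set, description, genes) {
    paste(c(set, description, genes), collapse = "\t")
  })
  readr::write_lines(unlist(lines, use.names = FALSE) %||% character(), path)
  invisible(path)
}

# Coerce a named list of gene vectors to the canonical gene-set tibble.
as_gene_sets <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("set", "genes") %in% names(sets)))
    if (!"description" %in% names(sets)) sets$description <- sets$set
    return(sets[c("set", "description", "genes")])
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  tibble(set = names(sets), description = names(sets),
         genes = unname(map(sets, as.character)))
}

# Named list view of a gene-set tibble, used by the scoring engine.
gene_set_list <- function(sets) {
  sets <- as_gene_sets(sets)
  setNames(sets$genes, sets$set)
}

#' Read or write per-sample annotations
#'
#' Annotation tables carry one row per sequenced sample: `sample_id`,
#' `patient_id`, `tissue` (one of `C` primary colorectal lesion, `L` liver
#' metastasis, `Ln` tumor-distant normal liver) and `hgp` (the patient's
#' histopathological growth pattern: `dHGP`, `rHGP`, `impure` or
#' `unknown`). Each patient has at most one `C` and one `Ln` sample; `L`
#' may repeat across lesions.
#'
#' @param path TSV path.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann Annotation tibble.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(validate_annotation(ann), path, progress = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  need <- c("sample_id", "patient_id", "tissue", "hgp")
  if (!all(need %in% names(ann))) {
    abort(paste0("annotation must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ann$sample_id)) abort("duplicate sample_id in annotation")
  bad_t <- setdiff(unique(ann$tissue), c("C", "L", "Ln"))
  if (length(bad_t)) abort(paste0("unknown tissue code: ", paste(bad_t, collapse = ", ")))
  bad_h <- setdiff(unique(ann$hgp), c("dHGP", "rHGP", "impure", "unknown"))
  if (length(bad_h)) abort(paste0("unknown HGP label: ", paste(bad_h, collapse = ", ")))
  once <- ann |>
    filter(.data$tissue %in% c("C", "Ln")) |>
    count(.data$patient_id, .data$tissue) |>
    filter(.data$n > 1)
  if (nrow(once) > 0) {
    abort(paste0("tissue ", once$tissue[1], " appears more than once for patient ",
                 once$patient_id[1]))
  }
  as_tibble(ann)
}

#' Read or write the clinical table
#'
#' One row per patient with categorical covariates plus the relapse-free
#' survival endpoint: `rfs_time_months` (time from curative operation to
#' first relapse or last follow-up) and `rfs_event` (0/1).
#'
#' @param path TSV path.
#' @return A clinical tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(cl)
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(validate_clinical(clinical), path, progress = FALSE)
  invisible(path)
}

validate_clinical <- function(clinical) {
  need <- c("patient_id", "rfs_time_months", "rfs_event")
  if (!all(need %in% names(clinical))) {
    abort(paste0("clinical table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(clinical$rfs_time_months)) || any(clinical$rfs_time_months < 0)) {
    abort("rfs_time_months must be finite and non-negative")
  }
  ev <- as.logical(clinical$rfs_event)
  if (any(is.na(ev))) abort("rfs_event must be 0/1 or logical")
  if (any(ev & clinical$rfs_time_months <= 0)) {
    abort("a relapse event requires rfs_time_months > 0")
  }
  clinical$rfs_event <- ev
  as_tibble(clinical)
}

#' Restrict an expression table to annotated samples of one tissue
#'
#' Columns are returned in annotation order. Annotated samples of the
#' requested tissue that are missing from the expression table are dropped
#' with a warning naming the patients.
#'
#' @param expr Expression tibble.
#' @param ann Annotation tibble.
#' @param tissue One of `"C"`, `"L"`, `"Ln"`.
#' @return Expression tibble restricted to the requested samples.
#' @export
align_cohort <- function(expr, ann, tissue = c("C", "L", "Ln")) {
  tissue <- match.arg(tissue)
  ann <- validate_annotation(ann)
  wanted <- ann$sample_id[ann$tissue == tissue]
  present <- intersect(wanted, setdiff(names(expr), "gene_id"))
  missing <- setdiff(wanted, present)
  if (length(missing) > 0) {
    pats <- unique(ann$patient_id[ann$sample_id %in% missing])
    warn(paste0("dropping ", length(missing), " annotated ", tissue,
                " sample(s) absent from the expression table (patients: ",
                paste(head(pats, 5), collapse = ", "), ")"))
  }
  if (length(present) == 0) {
    abort(paste0("no ", tissue, " samples present in the expression table"))
  }
  expr[c("gene_id", present)]
}
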