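# Readers/writers for every external format the pipeline touches, with strict
# validation: TSV feature-by-sample matrices, VCF dosages, GMT-like region
# sets, BED-like feature annotation and the sample sheet.

MATRIX_KINDS <- c("methylation", "expression", "dosage", "hla")

#' Construct and validate a molecular matrix
#'
#' A molecular matrix is a dense feature-by-sample numeric matrix carrying a
#' `kind` attribute. Kind-specific range checks: methylation betas in
#' \[0, 1\]; expression counts non-negative integers; dosages (SNP or HLA) in
#' \[0, 2\]. Missing values are permitted only for dosage-kind matrices.
#'
#' @param values Numeric matrix, features in rows (rownames) and samples in
#'   columns (colnames).
#' @param kind One of `"methylation"`, `"expression"`, `"dosage"`, `"hla"`.
#' @return The validated matrix with a `kind` attribute.
#' @export
molecular_matrix <- function(values, kind) {
  kind <- match.arg(kind, MATRIX_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    rlang::abort("Molecular matrices need feature rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    rlang::abort(paste0("Duplicated feature id: ", dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    rlang::abort(paste0("Duplicated sample id: ", dup))
  }
  if (anyNA(values) && !kind %in% c("dosage", "hla")) {
    rlang::abort(paste0("Missing values are not permitted for kind '", kind, "'."))
  }
  v <- values[!is.na(values)]
  ok <- switch(kind,
    methylation = all(v >= 0 & v <= 1),
    expression  = all(v >= 0) && all(abs(v - round(v)) < 1e-8),
    dosage      = all(v >= 0 & v <= 2),
    hla         = all(v >= 0 & v <= 2))
  if (!ok) {
    rlang::abort(paste0("Values out of range for kind '", kind, "'."))
  }
  attr(values, "kind") <- kind
  values
}

#' Read or write a feature-by-sample matrix as TSV
#'
#' The TSV contract is a header row of sample ids with the first column
#' holding feature ids. `write_matrix()` followed by `read_matrix()` is the
#' identity up to float formatting (12 significant digits).
#'
#' @param path File path.
#' @param kind Matrix kind, see [molecular_matrix()].
#' @return `read_matrix()` returns a validated molecular matrix.
#' @export
read_matrix <- function(path, kind) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) rlang::abort("Matrix TSV needs a feature-id column plus samples.")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  molecular_matrix(m, kind)
}

#' @rdname read_matrix
#' @param matrix A molecular matrix (or plain numeric matrix with dimnames).
#' @export
write_matrix <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "feature_id")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read allele dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise the ALT allele count of
#' the `GT` field. Missing genotypes become missing dosages. Multi-allelic
#' records are rejected. Positions are the 1-based VCF `POS`.
#'
#' @param path Path to a VCF (v4.x, plain text or gzipped).
#' @return A list with `dosages` (molecular matrix, kind `"dosage"`) and
#'   `annotation` (tibble: feature_id, chrom, pos).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    bad <- fix[grepl(",", alt), "ID"][1]
    rlang::abort(paste0("Multi-allelic record not supported (e.g. ", bad, ")."))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      a <- strsplit(gsub("\\|", "/", col), "/")
      vapply(a, function(x) {
        if (length(x) == 0 || anyNA(x) || any(x == ".")) return(NA_real_)
        sum(x != "0")
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(fix))
  }
  rownames(ds) <- ids
  colnames(ds) <- colnames(v@gt)[-1]
  ann <- tibble::tibble(feature_id = ids,
                        chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]))
  list(dosages = molecular_matrix(ds, "dosage"), annotation = ann)
}

#' Write hard-call or fractional dosages as a minimal VCF
#'
#' Emits a VCF v4.2 with a `DS` FORMAT field (and `GT` hard calls when all
#' dosages are integral), suitable for round-tripping through
#' [read_vcf_dosages()].
#'
#' @param dosages Dosage molecular matrix (SNP x sample).
#' @param annotation Tibble with feature_id, chrom, pos (ref/alt optional).
#' @param path Output path.
#' @export
write_vcf_dosages <- function(dosages, annotation, path) {
  ann <- annotation[match(rownames(dosages), annotation$feature_id), ]
  hard <- all(abs(dosages - round(dosages)) < 1e-9, na.rm = TRUE)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(dosages)), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(dosages)), function(i) {
    d <- dosages[i, ]
    cell <- if (hard) {
      ifelse(is.na(d), "./.:.", paste0(gt_of[round(d) + 1], ":", format(d)))
    } else {
      ifelse(is.na(d), ".", format(signif(d, 6)))
    }
    fmtkey <- if (hard) "GT:DS" else "DS"
    ref <- if ("ref" %in% names(ann)) ann$ref[i] else "A"
    alt <- if ("alt" %in% names(ann)) ann$alt[i] else "G"
    paste(c(ann$chrom[i], ann$pos[i], ann$feature_id[i], ref, alt,
            ".", "PASS", ".", fmtkey, cell), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write region sets in GMT-like format
#'
#' Each line is `region_id<TAB>kind<TAB>cpg1<TAB>cpg2...` where kind is one of
#' `promoter`, `gene_body`, `CGI`.
#'
#' @param path File path.
#' @return A tibble with columns region_id, region_kind and a `members`
#'   list-column of CpG ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kinds <- c("promoter", "gene_body", "CGI")
  out <- purrr::map(parts, function(p) {
    if (length(p) < 3) rlang::abort("GMT line needs id, kind and >= 1 member.")
    if (!p[2] %in% kinds) {
      rlang::abort(paste0("Unknown region kind '", p[2], "' (expected ",
                          paste(kinds, collapse = "/"), ")."))
    }
    tibble::tibble(region_id = p[1], region_kind = p[2], members = list(p[-(1:2)]))
  })
  sets <- dplyr::bind_rows(out)
  if (anyDuplicated(paste(sets$region_kind, sets$region_id))) {
    rlang::abort("Duplicate region_id within a region kind.")
  }
  sets
}

#' @rdname read_gmt
#' @param region_sets Tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(region_sets, path) {
  lines <- purrr::pmap_chr(region_sets, function(region_id, region_kind, members, ...) {
    paste(c(region_id, region_kind, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

SHEET_MANDATORY <- c("sample_id", "disease", "sex", "age")

#' Read or write the per-sample metadata sheet
#'
#' Validates the sheet contract: mandatory columns (`sample_id`, `disease`,
#' `sex`, `age`), unique sample ids, `disease` in case/control, cell
#' proportions (columns `cell_*`) in \[0, 1\] summing to at most 1.
#'
#' @param path TSV path.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(validate_sample_sheet(sheet), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  missing <- setdiff(SHEET_MANDATORY, names(sheet))
  if (length(missing) > 0) {
    rlang::abort(paste0("Sample sheet missing mandatory column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) rlang::abort("Duplicate sample ids in sheet.")
  if (!all(sheet$disease %in% c("case", "control"))) {
    rlang::abort("`disease` must be 'case' or 'control'.")
  }
  cells <- grep("^cell_", names(sheet), value = TRUE)
  if (length(cells) > 0) {
    cm <- as.matrix(sheet[, cells])
    if (any(cm < 0 | cm > 1)) rlang::abort("Cell proportions must lie in [0, 1].")
    if (any(rowSums(cm) > 1 + 1e-6)) rlang::abort("Cell proportions sum above 1.")
  }
  tibble::as_tibble(sheet)
}

#' Read or write BED-like feature annotation
#'
#' One row per feature with 1-based coordinates: `feature_id`, `chrom`,
#' `pos` (CpG coordinate, gene TSS, or SNP position), optional `strand`
#' (genes), `gene_label` and `region_class`.
#'
#' @param path TSV path.
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("feature_id", "chrom", "pos")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    rlang::abort(paste0("Annotation missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(ann$pos < 1)) rlang::abort("Annotation positions must be >= 1 (1-based).")
  if (any(!nzchar(ann$chrom))) rlang::abort("Empty chromosome name in annotation.")
  ann
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  invisible(path)
}

#' Write a results table with a stable column order
#'
#' @param table Result tibble from any scan.
#' @param path Output TSV path.
#' @export
write_results <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Transcription start site of a gene interval
#'
#' Strand-aware anchor used for cis-window tests: plus-strand genes anchor at
#' the lower coordinate, minus-strand genes at the higher coordinate.
#'
#' @param start,end 1-based interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return TSS position(s).
#' @export
tss_position <- function(start, end, strand) {
  ifelse(strand == "-", pmax(start, end), pmin(start, end))
}
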