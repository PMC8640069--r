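# Internal helpers shared across scans: design-matrix construction,
# sample alignment, and logit-scale effect calibration for the simulator.

#' Describe the covariate model used by the association scans
#'
#' A model specification is a named list of covariate column names taken from
#' the sample sheet. The token `"cells"` expands to every `cell_*` proportion
#' column with the last one dropped, avoiding the sum-to-one collinearity.
#' Character or factor columns (e.g. `batch`, `pool`) enter as treatment-coded
#' dummies; logical and numeric columns enter as-is.
#'
#' @param covariates Character vector of sample-sheet column names (the token
#'   `"cells"` expands to the cell-proportion block).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(c("sex", "age", "pc1", "cells", "batch"))
model_spec <- function(covariates = c("sex", "age", "pc1", "cells", "batch")) {
  structure(list(covariates = as.character(covariates)), class = "model_spec")
}

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) return(x)
  if (is.character(x)) return(model_spec(x))
  rlang::abort("`model_spec` must be a model_spec object or a character vector.")
}

expand_covariate_names <- function(sheet, covariates) {
  out <- character(0)
  for (cv in covariates) {
    if (identical(cv, "cells")) {
      cells <- grep("^cell_", names(sheet), value = TRUE)
      if (length(cells) == 0) {
        rlang::abort("model_spec requests 'cells' but sheet has no cell_* columns.")
      }
      out <- c(out, cells[-length(cells)])  # drop one to break sum-to-one
    } else {
      if (!cv %in% names(sheet)) {
        rlang::abort(paste0("Covariate '", cv, "' not found in sample sheet."))
      }
      out <- c(out, cv)
    }
  }
  unique(out)
}

# Build a design matrix (with intercept) from sheet columns.
# `extra` is a named list of numeric columns appended verbatim (dosage, group).
build_design <- function(sheet, covariates, extra = list()) {
  cols <- expand_covariate_names(sheet, covariates)
  if (length(cols) > 0) {
    df <- as.data.frame(sheet[, cols, drop = FALSE])
    chr <- vapply(df, function(x) is.character(x) || is.logical(x), logical(1))
    df[chr] <- lapply(df[chr], as.factor)
    X <- stats::model.matrix(~ ., data = df)
  } else {
    X <- matrix(1, nrow(sheet), 1, dimnames = list(NULL, "(Intercept)"))
  }
  for (nm in names(extra)) {
    X <- cbind(X, stats::setNames(data.frame(extra[[nm]]), nm)[[1]])
    colnames(X)[ncol(X)] <- nm
  }
  check_full_rank(X)
  X
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    rlang::abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                        paste(bad, collapse = ", ")))
  }
  invisible(X)
}

disease_indicator <- function(sheet) {
  as.numeric(sheet$disease == "case")
}

#' Align molecular matrices with a sample sheet
#'
#' Intersects the sample ids of one or more matrices with the sheet and
#' returns everything restricted to the shared samples, preserving sheet
#' order. Mismatched sample sets are an error unless `allow_subset = TRUE`.
#'
#' @param sheet Sample-sheet tibble with a `sample_id` column.
#' @param ... Named matrices with sample ids as column names.
#' @param allow_subset Permit samples present in only some inputs.
#' @return A list with the subset `sheet` and each aligned matrix.
#' @export
align_samples <- function(sheet, ..., allow_subset = FALSE) {
  mats <- list(...)
  ids <- sheet$sample_id
  for (m in mats) ids <- intersect(ids, colnames(m))
  full <- all(vapply(mats, function(m) setequal(colnames(m), sheet$sample_id),
                     logical(1)))
  if (!full && !allow_subset) {
    rlang::abort("Sample ids differ across inputs; use allow_subset = TRUE to intersect.")
  }
  if (length(ids) == 0) rlang::abort("No shared samples after alignment.")
  ids <- sheet$sample_id[sheet$sample_id %in% ids]  # sheet order
  out <- lapply(mats, function(m) m[, ids, drop = FALSE])
  out$sheet <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  out
}

# --- logit-scale calibration -------------------------------------------------

# E[plogis(l + sigma Z)], Z ~ N(0,1), vectorised over l (fixed quadrature grid).
.gauss_grid <- {
  z <- seq(-6, 6, length.out = 201)
  w <- exp(-z^2 / 2)
  list(z = z, w = w / sum(w))
}

expected_beta <- function(l, sigma) {
  z <- .gauss_grid$z; w <- .gauss_grid$w
  vapply(l, function(li) sum(w * stats::plogis(li + sigma * z)), numeric(1))
}

# Logit shift d such that E[beta | shift d] - E[beta | no shift] = delta,
# holding the noise sd fixed. Keeps planted beta-scale effect sizes honest
# despite the Jensen shrinkage of the inverse-logit.
calibrate_logit_shift <- function(base_beta, delta, sigma) {
  l0 <- stats::qlogis(base_beta)
  target <- expected_beta(l0, sigma) + delta
  if (target <= 1e-4 || target >= 1 - 1e-4) {
    rlang::abort("Planted beta-scale effect pushes the mean outside (0,1).")
  }
  f <- function(d) expected_beta(l0 + d, sigma) - target
  stats::uniroot(f, c(-25, 25), tol = 1e-9)$root
}
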