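# Internal helpers shared across modules.

# Average days per calendar month; also the month-binning divisor used in
# validation stratification.
DAYS_PER_MONTH <- 30.44

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed from a master seed and an index; kept below 2^31.
child_seed <- function(master_seed, index) {
  (as.double(master_seed) + as.double(index)) %% 2147483629
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

# Dummy-encode a mixed-type feature data.frame into a numeric matrix.
# `encoder = NULL` learns factor levels from the data; pass a stored encoder
# to guarantee identical columns at prediction time.
encode_features <- function(df, encoder = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(encoder)) {
    encoder <- list(columns = names(df), levels = lapply(df, function(col) {
      if (is.factor(col) || is.character(col)) levels(as.factor(col)) else NULL
    }))
  }
  missing_cols <- setdiff(encoder$columns, names(df))
  if (length(missing_cols)) {
    stop("feature table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mats <- lapply(encoder$columns, function(nm) {
    col <- df[[nm]]
    lv <- encoder$levels[[nm]]
    if (is.null(lv)) {
      m <- matrix(as.numeric(col), ncol = 1L)
      colnames(m) <- nm
      return(m)
    }
    f <- factor(col, levels = lv)
    if (anyNA(f) && !anyNA(col)) {
      stop(sprintf("column '%s' has levels unseen at fit time", nm), call. = FALSE)
    }
    if (length(lv) < 2L) {
      m <- matrix(0, nrow = length(f), ncol = 1L)
      colnames(m) <- paste0(nm, lv[1L])
      return(m)
    }
    m <- vapply(lv[-1L], function(l) as.numeric(f == l), numeric(length(f)))
    m <- matrix(m, nrow = length(f))
    colnames(m) <- paste0(nm, lv[-1L])
    m
  })
  x <- do.call(cbind, mats)
  rownames(x) <- NULL
  list(x = x, encoder = encoder)
}

# Format doubles so that CSV round-trips are lossless (%.17g reproduces the
# exact binary double); integers and strings pass through.
format_lossless <- function(df) {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- NA_character_
      out[[nm]] <- s
    } else if (is.logical(col) || is.factor(col)) {
      out[[nm]] <- as.character(col)
    }
  }
  out
}
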