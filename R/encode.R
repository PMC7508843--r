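#' Fit the visit-encoding schema on a training split
#'
#' Continuous covariates (the 15 internally computed imaging features plus
#' age and visual acuity) are z-scored with training-split statistics.
#' Categorical demographics (gender, race, smoking status) are one-hot
#' encoded with an explicit `missing` level, so cohorts lacking a column
#' (e.g. a clinic export without race/smoking) encode cleanly. The schema
#' must be fitted on the training split only and reused unchanged on
#' validation/test data.
#'
#' @param visits training visit rows (dry observations with features).
#' @param continuous names of continuous columns; default imaging features +
#'   `age_months` + `visual_acuity`.
#' @param categorical named list of canonical level sets.
#' @return an `encoder_schema`.
#' @export
fit_encoder <- function(visits,
                        continuous = c(feature_names(FALSE), "age_months",
                                       "visual_acuity"),
                        categorical = list(
                          gender = c("male", "female"),
                          race = c("white", "black", "asian",
                                   "native_american", "pacific_islander"),
                          smoking_status = c("never", "previous", "current")
                        )) {
  missing_cont <- setdiff(continuous, names(visits))
  assert_that(length(missing_cont) == 0,
              paste("missing continuous columns:",
                    paste(missing_cont, collapse = ", ")))
  mu <- vapply(continuous, function(cn) {
    mean(visits[[cn]], na.rm = TRUE)
  }, 0)
  sdv <- vapply(continuous, function(cn) {
    s <- stats::sd(visits[[cn]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  }, 0)
  cols <- c(continuous,
            unlist(lapply(names(categorical), function(g) {
              paste0(g, "=", c(categorical[[g]], "missing"))
            }), use.names = FALSE))
  structure(
    list(continuous = continuous, mu = mu, sd = sdv,
         categorical = categorical, columns = cols, dim = length(cols)),
    class = "encoder_schema"
  )
}

#' Encode visit rows to the model's numeric feature matrix
#'
#' @param schema an `encoder_schema` from [fit_encoder()].
#' @param visits visit rows to encode (any split).
#' @return numeric matrix, one row per visit, `schema$dim` columns; finite
#'   everywhere (missing continuous values are imputed at the training mean,
#'   i.e. encode to 0 after z-scoring).
#' @export
encode_visits <- function(schema, visits) {
  stopifnot(inherits(schema, "encoder_schema"))
  n <- nrow(visits)
  X <- matrix(0, n, schema$dim, dimnames = list(NULL, schema$columns))
  for (cn in schema$continuous) {
    v <- if (cn %in% names(visits)) visits[[cn]] else rep(NA_real_, n)
    v <- (v - schema$mu[[cn]]) / schema$sd[[cn]]
    v[!is.finite(v)] <- 0
    X[, cn] <- v
  }
  for (g in names(schema$categorical)) {
    lv <- schema$categorical[[g]]
    val <- if (g %in% names(visits)) as.character(visits[[g]]) else
      rep(NA_character_, n)
    unseen <- !is.na(val) & !(val %in% lv)
    if (any(unseen)) {
      warning(sprintf("%d unseen '%s' level(s) mapped to missing", sum(unseen),
                      g), call. = FALSE)
      val[unseen] <- NA_character_
    }
    for (l in lv) X[, paste0(g, "=", l)] <- as.numeric(!is.na(val) & val == l)
    X[, paste0(g, "=missing")] <- as.numeric(is.na(val))
  }
  X
}

#' Decode the categorical part of encoded visits
#'
#' Inverse of the one-hot block of [encode_visits()]; continuous columns are
#' returned de-z-scored. Used for schema round-trip checks.
#'
#' @param schema an `encoder_schema`.
#' @param X encoded matrix.
#' @return data.frame with the categorical levels (`NA` for missing) and the
#'   reconstructed continuous columns.
#' @export
decode_visits <- function(schema, X) {
  stopifnot(inherits(schema, "encoder_schema"))
  out <- as.data.frame(
    lapply(schema$continuous,
           function(cn) X[, cn] * schema$sd[[cn]] + schema$mu[[cn]])
  )
  names(out) <- schema$continuous
  for (g in names(schema$categorical)) {
    lv <- c(schema$categorical[[g]], "missing")
    block <- X[, paste0(g, "=", lv), drop = FALSE]
    pick <- lv[max.col(block)]
    pick[pick == "missing"] <- NA_character_
    out[[g]] <- pick
  }
  out
}
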