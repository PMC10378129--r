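# Serialization glue: recurrence families and model parameter files in a
# restricted JSON/YAML dialect, plus TSV writers for spectra and
# distributions.

# safe arithmetic-expression parser: literals, the symbol j, + - * / ^ ( )
.safe_expr_check <- function(e) {
  if (is.numeric(e) || is.integer(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    if (identical(as.character(e), "j")) return(invisible(TRUE))
    stop("expression may only use the variable 'j' (found '",
         as.character(e), "')", call. = FALSE)
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% c("+", "-", "*", "/", "^", "("))
      stop("operator or function '", op, "' not allowed in coefficient ",
           "expressions", call. = FALSE)
    for (k in seq_along(e)[-1L]) .safe_expr_check(e[[k]])
    return(invisible(TRUE))
  }
  stop("unsupported element in coefficient expression", call. = FALSE)
}

#' Parse a restricted coefficient expression
#'
#' Compiles a plain arithmetic expression in the row index `j` (operators
#' `+ - * / ^` and parentheses only; no function calls, no other
#' variables) into a coefficient rule.  This is the expression grammar of
#' the recurrence JSON dialect; it deliberately excludes general code
#' execution.
#'
#' @param text expression source, e.g. `"(j+1)*(j+2)"`.
#' @return A function of `j`.
#' @export
parse_coefficient_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- str2lang(text)
  .safe_expr_check(e)
  function(j) eval(e, list(j = j))
}

#' Serialize a recurrence family to JSON
#'
#' Tables (plain or rational) are written verbatim; rule-based families
#' must be given their expression source through `exprs` (a named list
#' with entries of `P`, `Qt`, `R`).
#'
#' @param rec a [three_term_recurrence()] built from tables, or `exprs`
#'   supplied for rule-based families.
#' @param exprs optional named list of expression strings.
#' @param j_max when `exprs` is not supplied, rows `0..j_max` of the
#'   (table) family are serialized.
#' @return JSON string.
#' @export
ttr_to_json <- function(rec, exprs = NULL, j_max = NULL) {
  ov <- rec$overrides
  enc_ov <- if (length(ov)) {
    lapply(ov, function(o) lapply(o, function(v) v[1] / v[2]))
  } else NULL
  body <- if (!is.null(exprs)) {
    stopifnot(all(c("P", "Qt", "R") %in% names(exprs)))
    lapply(exprs, function(s) { parse_coefficient_rule(s); s })
  } else {
    stopifnot(!is.null(j_max))
    list(P = ttr_coef(rec, 0:j_max, "P"),
         Qt = ttr_coef(rec, 0:j_max, "Qt"),
         R = ttr_coef(rec, 0:j_max, "R"))
  }
  jsonlite::toJSON(c(body, list(overrides = enc_ov, mode = rec$mode)),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Deserialize a recurrence family from JSON
#'
#' @param json JSON string or path to a JSON file in the dialect written
#'   by [ttr_to_json()] / [generate_fixture()]: each of `P`, `Qt`, `R` is
#'   either a numeric array, a `{"num": [...], "den": [...]}` rational
#'   table, or an expression string in `j`.
#' @return A [three_term_recurrence()].
#' @export
ttr_from_json <- function(json) {
  x <- if (file.exists(json)) jsonlite::fromJSON(json) else jsonlite::fromJSON(json)
  fam <- lapply(x[c("P", "Qt", "R")], function(f) {
    if (is.character(f)) parse_coefficient_rule(f)
    else if (is.list(f) && !is.null(f$num)) list(num = f$num, den = f$den)
    else as.numeric(f)
  })
  ov <- NULL
  if (!is.null(x$overrides) && length(x$overrides))
    ov <- lapply(x$overrides, function(o) lapply(o, as.numeric))
  mode <- if (!is.null(x$mode)) x$mode else "double"
  three_term_recurrence(P = fam$P, Qt = fam$Qt, R = fam$R, overrides = ov,
                        mode = mode)
}

#' Read a model parameter file
#'
#' Accepts JSON (or YAML, if the yaml package is installed) files with a
#' `model` field of `"binary_choice"` or `"vacillating"` and the model
#' parameters.
#'
#' @param path file path.
#' @return A choice model object.
#' @export
read_model_file <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML input requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  model_from_list(x)
}

#' @rdname read_model_file
#' @param x a named list with a `model` field.
#' @export
model_from_list <- function(x) {
  switch(x$model,
    binary_choice = binary_choice_model(N = x$N, eps1 = x$eps1, eps2 = x$eps2,
                                        mu1 = x$mu1, mu2 = x$mu2),
    vacillating = vacillating_voter_model(N = x$N, pd = x$pd),
    stop("unknown model kind: ", x$model))
}

#' Serialize a choice model
#' @param model a choice model.
#' @return JSON string.
#' @export
model_to_json <- function(model) {
  kind <- if (inherits(model, "binary_choice_model")) "binary_choice"
          else "vacillating"
  jsonlite::toJSON(c(list(model = kind), unclass(model)),
                   auto_unbox = TRUE, digits = NA)
}

#' Write a spectrum table as TSV
#' @param spectrum decay rates or a [spectral_decomposition()] object.
#' @param file path to write to.
#' @export
write_spectrum_tsv <- function(spectrum, file) {
  lam <- if (inherits(spectrum, "ctmc_spectrum")) spectrum$decay_rates
         else as.numeric(spectrum)
  tab <- data.frame(i = seq_along(lam) - 1L, lambda = lam,
                    relaxation_time = ifelse(lam > 0, 1 / lam, Inf))
  utils::write.table(tab, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a time-evolved distribution as TSV
#' @param P matrix from [evolve()] (states x times).
#' @param times the times the columns correspond to.
#' @param file path to write to.
#' @export
write_distribution_tsv <- function(P, times, file) {
  tab <- data.frame(t = rep(times, each = nrow(P)),
                    n = rep(seq_len(nrow(P)) - 1L, times = length(times)),
                    P = as.numeric(P))
  utils::write.table(tab, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
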