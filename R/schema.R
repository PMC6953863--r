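#' Variable schema for a treatment-uptake cohort
#'
#' A `variable_schema` describes the layout of a cohort table: an ordered set
#' of feature variables (binary indicators, one-hot group members, ordinal
#' stages and one continuous age column) together with their marginal
#' probabilities or distribution parameters, plus the binary outcome and its
#' prevalence. It is the single source of truth for column order, encoding and
#' the marginals the synthetic generator draws from.
#'
#' @param variables data frame with columns `id`, `name`, `kind`
#'   (`"binary"`, `"onehot"`, `"ordinal"`, `"continuous"`), `group`
#'   (`NA` outside one-hot blocks), and `prob` (marginal success probability
#'   for binary / category probability for one-hot; `NA` for ordinal and
#'   continuous variables, which carry their parameters in `params`).
#' @param params named list of extra distribution parameters keyed by variable
#'   id (e.g. ordinal level probabilities, age `min`/`max`/`mean`/`sd`).
#' @param outcome list with `name`, `prevalence` (positive-class probability).
#' @return an object of class `variable_schema`.
#' @seealso [default_schema()] for the HERACLES-style layout.
#' @export
variable_schema <- function(variables, params = list(), outcome) {
  stopifnot(is.data.frame(variables),
            all(c("id", "name", "kind", "group", "prob") %in% names(variables)))
  schema <- structure(
    list(variables = variables, params = params, outcome = outcome),
    class = "variable_schema"
  )
  validate_schema(schema)
  schema
}

#' Validate a variable schema
#'
#' Checks the structural invariants: 17 feature variables and one outcome,
#' probabilities in \[0, 1\], one-hot groups closing to 1 (within 1e-12), and
#' an age distribution with `min < mean < max`.
#'
#' @param schema a `variable_schema`.
#' @return the schema, invisibly; stops on violation.
#' @export
validate_schema <- function(schema) {
  v <- schema$variables
  if (nrow(v) != 17L)
    stop("schema must declare exactly 17 feature variables, got ", nrow(v))
  pr <- v$prob[!is.na(v$prob)]
  if (any(pr < 0 | pr > 1))
    stop("marginal probabilities must lie in [0, 1]")
  for (g in unique(stats::na.omit(v$group))) {
    s <- sum(v$prob[!is.na(v$group) & v$group == g])
    if (abs(s - 1) > 1e-12)
      stop("one-hot group '", g, "' probabilities sum to ", s, ", not 1")
  }
  for (id in v$id[v$kind == "ordinal"]) {
    p <- schema$params[[id]]$level_probs
    if (is.null(p) || abs(sum(p) - 1) > 1e-12 || any(p < 0))
      stop("ordinal variable '", id, "' needs level_probs summing to 1")
  }
  for (id in v$id[v$kind == "continuous"]) {
    p <- schema$params[[id]]
    if (is.null(p) || !(p$min < p$mean && p$mean < p$max))
      stop("continuous variable '", id, "' needs min < mean < max")
    if (!is.finite(p$sd) || p$sd <= 0)
      stop("continuous variable '", id, "' needs a positive sd")
  }
  out <- schema$outcome
  if (!is.list(out) || is.null(out$prevalence) ||
      out$prevalence <= 0 || out$prevalence >= 1)
    stop("outcome prevalence must lie strictly inside (0, 1)")
  invisible(schema)
}

#' Default HERACLES-style schema
#'
#' Builds the 17-variable schema of the Spanish HERACLES HIV/HCV co-infection
#' cohort (N = 2940): prioritisation-criteria status, the four-category PWID
#' block, psychiatric disorder, incarceration, the three-category treatment
#' history block, an ordinal liver-fibrosis stage (1 = F0-F1 .. 4 = F4),
#' gender, age, the four-category HCV genotype block, and a treated/untreated
#' outcome with 66.4% prevalence. All marginals are the published cohort
#' frequencies over 2940 patients.
#'
#' @return a `variable_schema`.
#' @examples
#' sch <- default_schema()
#' subset(sch$variables, id == "X4")$prob  # recent PWID, 47/2940
#' @export
default_schema <- function() {
  n <- 2940
  vars <- data.frame(
    id   = paste0("X", 1:17),
    name = c("met_criteria", "lifetime_pwid", "ost_pwid", "recent_pwid",
             "never_pwid", "psychiatric_disorder", "been_in_jail",
             "naive_to_therapy", "peg_ifn_rbv", "daa_peg_ifn_rbv",
             "liver_fibrosis", "male", "age",
             "genotype_1", "genotype_2", "genotype_3", "genotype_4"),
    kind = c("binary", rep("onehot", 4), "binary", "binary",
             rep("onehot", 3), "ordinal", "binary", "continuous",
             rep("onehot", 4)),
    group = c(NA, rep("pwid", 4), NA, NA, rep("prev_treat", 3),
              NA, NA, NA, rep("genotype", 4)),
    prob = c(1653, 2169, 339, 47, 385, 54, 117, 2053, 725, 162,
             NA, 2449, NA, 1741, 27, 484, 688) / n,
    stringsAsFactors = FALSE
  )
  vars$prob[vars$kind %in% c("ordinal", "continuous")] <- NA_real_
  params <- list(
    X11 = list(level_probs = c(898, 475, 787, 780) / n, levels = 1:4),
    X13 = list(min = 18, max = 76, mean = 48.95, sd = 8)
  )
  variable_schema(vars, params,
                  outcome = list(name = "y", prevalence = 1952 / n))
}

#' @export
print.variable_schema <- function(x, ...) {
  v <- x$variables
  cat("variable_schema: 17 features + outcome '", x$outcome$name, "'\n", sep = "")
  cat(sprintf("  positive-class prevalence: %.4f\n", x$outcome$prevalence))
  cat(sprintf("  %d binary, %d one-hot (%d groups), %d ordinal, %d continuous\n",
              sum(v$kind == "binary"), sum(v$kind == "onehot"),
              length(unique(stats::na.omit(v$group))),
              sum(v$kind == "ordinal"), sum(v$kind == "continuous")))
  invisible(x)
}

#' Map a liver stiffness measurement to a fibrosis stage
#'
#' Transient elastography (FibroScan) stiffness in kPa is staged as
#' F0-F1 below 7.2, F2 from 7.2 up to (but excluding) 9, F3 from 9 up to
#' (but excluding) 14.6, and F4 at or above 14.6. The published band edges
#' leave the intervals \[8.9, 9) and \[14.5, 14.6) uncovered; values falling
#' there are assigned to the lower stage (conservative staging), which makes
#' the four stages a partition of the positive axis.
#'
#' @param lsm_kpa numeric vector of positive, finite stiffness values (kPa).
#' @return character vector of stage labels in
#'   `c("F0-F1", "F2", "F3", "F4")`.
#' @examples
#' stage_fibrosis(c(7.1, 7.2, 8.95, 9, 14.5, 14.6))
#' @export
stage_fibrosis <- function(lsm_kpa) {
  if (!is.numeric(lsm_kpa) || any(!is.finite(lsm_kpa)) || any(lsm_kpa <= 0))
    stop("lsm_kpa must be positive and finite")
  cut(lsm_kpa, breaks = c(0, 7.2, 9, 14.6, Inf), right = FALSE,
      labels = c("F0-F1", "F2", "F3", "F4")) |> as.character()
}
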