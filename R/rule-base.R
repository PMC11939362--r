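#' Construct a fuzzy rule
#'
#' A rule maps an antecedent — for each of the four input factors, the set of
#' grades it may take (`AC`, "any condition", stands for all five) — to a
#' single consequent suitability grade.
#'
#' @param substrate,temperature,velocity,depth character vectors of allowed
#'   grades for each factor (subsets of `VL`,`L`,`M`,`H`,`VH`).
#' @param consequent single output grade.
#' @return an object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(substrate, temperature, velocity, depth, consequent) {
  ante <- list(substrate = substrate, temperature = temperature,
               velocity = velocity, depth = depth)
  for (f in FACTORS) {
    g <- unique(as.character(ante[[f]]))
    if (!length(g) || !all(g %in% GRADES))
      .stopf("rule: invalid grade(s) for %s: %s", f, paste(ante[[f]], collapse = "/"))
    ante[[f]] <- g
  }
  if (length(consequent) != 1L || !consequent %in% GRADES)
    .stopf("rule: consequent must be a single grade")
  structure(list(antecedent = ante, consequent = consequent), class = "fuzzy_rule")
}

.parse_token <- function(tok, line) {
  if (tok == "AC") return(GRADES)
  g <- strsplit(tok, "/", fixed = TRUE)[[1]]
  if (!length(g) || !all(g %in% GRADES))
    .stopf("rule file line %d: bad token '%s'", line, tok)
  g
}

#' Construct a rule base
#'
#' @param rules list of [fuzzy_rule()] objects.
#' @param provenance `"4-factor"` for the substrate-inclusive model or
#'   `"3-factor-baseline"` for the substrate-free baseline.
#' @return an object of class `rule_base`.
#' @export
rule_base <- function(rules, provenance = c("4-factor", "3-factor-baseline")) {
  provenance <- match.arg(provenance)
  if (!length(rules)) .stopf("rule base is empty")
  stopifnot(all(vapply(rules, inherits, logical(1), "fuzzy_rule")))
  rb <- structure(list(rules = rules, provenance = provenance),
                  class = "rule_base")
  .check_rule_conflicts(rb)
  rb
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("rule base (%s): %d rules\n", x$provenance, length(x$rules)))
  for (r in x$rules) {
    tok <- vapply(FACTORS, function(f) {
      g <- r$antecedent[[f]]
      if (length(g) == 5L) "AC" else paste(g, collapse = "/")
    }, character(1))
    cat(" ", paste(tok, collapse = " "), "->", r$consequent, "\n")
  }
  invisible(x)
}

#' Read a rule base from a plain-text rule file
#'
#' One rule per line: four antecedent tokens (substrate, temperature,
#' velocity, depth) and the consequent grade, with `/` separating grade
#' alternatives, `AC` for the entire fuzzy set of a factor, and `#` starting
#' comments. The format is token-compatible with the published rule table.
#'
#' @param path rule file path.
#' @param provenance see [rule_base()].
#' @return a [rule_base()].
#' @export
read_rule_base <- function(path, provenance = "4-factor") {
  if (!file.exists(path)) .stopf("rule file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) != 5L)
      .stopf("rule file line %d: expected 4 antecedent tokens + consequent", i)
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      substrate = .parse_token(tok[1], i), temperature = .parse_token(tok[2], i),
      velocity = .parse_token(tok[3], i), depth = .parse_token(tok[4], i),
      consequent = tok[5])
  }
  rule_base(rules, provenance)
}

#' Default four-factor rule base
#'
#' Loads the packaged rule file: the thirteen published rows plus two flagged
#' completion rows (boulder-bed blocking, and the all-marginal combination)
#' that make the base cover every grade combination.
#'
#' @return a [rule_base()] with provenance `"4-factor"`.
#' @export
default_rule_base <- function() {
  read_rule_base(system.file("extdata", "rules_4factor.txt",
                             package = "spawnhab", mustWork = TRUE),
                 provenance = "4-factor")
}

#' Expand a rule base over single-grade antecedents
#'
#' Expands every `/` list and `AC` wildcard by cartesian product into rules
#' whose antecedents hold exactly one grade per factor. Used for completeness
#' checking and baseline construction; inference itself works on the compact
#' form.
#'
#' @param rb a [rule_base()].
#' @return data.frame with columns `substrate`, `temperature`, `velocity`,
#'   `depth`, `consequent`, one row per expanded rule (duplicates removed).
#' @export
expand_rules <- function(rb) {
  stopifnot(inherits(rb, "rule_base"))
  out <- do.call(rbind, lapply(rb$rules, function(r) {
    g <- expand.grid(substrate = r$antecedent$substrate,
                     temperature = r$antecedent$temperature,
                     velocity = r$antecedent$velocity,
                     depth = r$antecedent$depth,
                     stringsAsFactors = FALSE)
    g$consequent <- r$consequent
    g
  }))
  unique(out)
}

# same antecedent mapping to different consequents is a configuration error
.check_rule_conflicts <- function(rb) {
  ex <- expand_rules(rb)
  key <- do.call(paste, ex[FACTORS])
  dup <- key[duplicated(key)]
  if (length(dup))
    .stopf("conflicting rules: antecedent '%s' maps to multiple consequents", dup[1])
  invisible(TRUE)
}

#' Check rule-base completeness by exhaustive enumeration
#'
#' Enumerates every grade combination over the given factors and verifies at
#' least one rule matches each. The four-factor base is checked over all
#' 5^4 combinations; the baseline over the 5^3 non-substrate combinations.
#'
#' @param rb a [rule_base()].
#' @param factors factors to enumerate over (default: all four for a
#'   4-factor base, the three hydraulic factors for a baseline).
#' @return `TRUE` invisibly, or an error listing the first uncovered
#'   combination.
#' @export
check_completeness <- function(rb, factors = NULL) {
  stopifnot(inherits(rb, "rule_base"))
  if (is.null(factors))
    factors <- if (rb$provenance == "3-factor-baseline")
      setdiff(FACTORS, "substrate") else FACTORS
  combos <- expand.grid(rep(list(GRADES), length(factors)),
                        stringsAsFactors = FALSE)
  names(combos) <- factors
  for (i in seq_len(nrow(combos))) {
    hit <- any(vapply(rb$rules, function(r)
      all(vapply(factors, function(f)
        combos[i, f] %in% r$antecedent[[f]], logical(1))), logical(1)))
    if (!hit)
      .stopf("rule base does not cover combination (%s)",
             paste(sprintf("%s=%s", factors, combos[i, ]), collapse = ", "))
  }
  invisible(TRUE)
}
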