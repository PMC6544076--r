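#' Read and write benefit-risk configurations as JSON
#'
#' Schema: `{"attributes": [{name, direction, worst, best, units, label}],
#' "alternatives": [{name, performance: {attr: {mean, ci_low, ci_high}}}]}`.
#' Writing then reading reproduces the configuration exactly.
#'
#' @param path file path.
#' @return [read_bra_config()] returns a `bra_config`;
#'   [write_bra_config()] returns `path` invisibly.
#' @export
read_bra_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$attributes) || is.null(doc$alternatives))
    stop("config must contain 'attributes' and 'alternatives'")
  af <- function(field, default = NULL)
    vapply(doc$attributes, function(a) {
      if (is.null(a[[field]])) {
        if (is.null(default)) stop("attribute missing field '", field, "'")
        default(a)
      } else a[[field]]
    }, if (field %in% c("worst", "best")) numeric(1) else character(1))
  attrs <- attribute_set(
    name = af("name"), direction = af("direction"),
    worst = af("worst"), best = af("best"), units = af("units"),
    label = af("label", default = function(a) a$name)
  )
  alts <- list()
  for (alt in doc$alternatives) {
    if (is.null(alt$name)) stop("alternative missing 'name'")
    perf <- alt$performance
    unknown <- setdiff(names(perf), attrs$name)
    if (length(unknown))
      stop("alternative '", alt$name, "' has unknown attributes: ",
           paste(unknown, collapse = ", "))
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    alts[[alt$name]] <- data.frame(
      attribute = names(perf),
      mean = unname(vapply(perf, function(p) num(p$mean), numeric(1))),
      ci_low = unname(vapply(perf, function(p) num(p$ci_low), numeric(1))),
      ci_high = unname(vapply(perf, function(p) num(p$ci_high), numeric(1))),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  tf <- if (is.null(doc$transforms)) list() else doc$transforms
  bra_config(attrs, alts, transforms = tf)
}

#' @rdname read_bra_config
#' @param config a [bra_config()].
#' @export
write_bra_config <- function(config, path) {
  attrs <- lapply(seq_len(nrow(config$attributes)), function(i) {
    a <- config$attributes[i, ]
    list(name = a$name, label = a$label, direction = a$direction,
         worst = a$worst, best = a$best, units = a$units)
  })
  alts <- lapply(names(config$alternatives), function(alt) {
    p <- config$alternatives[[alt]]
    perf <- lapply(seq_len(nrow(p)), function(i) {
      e <- list(mean = p$mean[i])
      if (!is.na(p$ci_low[i])) e$ci_low <- p$ci_low[i]
      if (!is.na(p$ci_high[i])) e$ci_high <- p$ci_high[i]
      e
    })
    names(perf) <- p$attribute
    list(name = alt, performance = perf)
  })
  doc <- list(attributes = attrs, alternatives = alts)
  if (length(config$transforms)) doc$transforms <- config$transforms
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write respondent panels as CSV
#'
#' Long form has columns `respondent_id`, `age_group`, `attribute`, `mir`,
#' `censored`, `straight_liner`; wide form one row per respondent with
#' `mir_<attribute>` columns (censoring flags are not representable in wide
#' form and default to `FALSE`). Both round-trip through these functions.
#'
#' @param path file path.
#' @return a long-format panel data frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("respondent_id", "attribute", "mir") %in% names(df))) {
    if (is.null(df$age_group)) df$age_group <- NA_character_
    if (is.null(df$censored)) df$censored <- FALSE
    if (is.null(df$straight_liner)) df$straight_liner <- FALSE
    df$censored <- as.logical(df$censored)
    df$straight_liner <- as.logical(df$straight_liner)
  } else if (any(startsWith(names(df), "mir_"))) {
    mir_cols <- names(df)[startsWith(names(df), "mir_")]
    long <- do.call(rbind, lapply(mir_cols, function(cn) {
      data.frame(respondent_id = df$respondent_id,
                 age_group = if (is.null(df$age_group)) NA_character_
                             else df$age_group,
                 attribute = sub("^mir_", "", cn),
                 mir = df[[cn]],
                 censored = FALSE,
                 straight_liner = if (is.null(df$straight_liner)) FALSE
                                  else as.logical(df$straight_liner),
                 stringsAsFactors = FALSE)
    }))
    df <- long[!is.na(long$mir), ]
  } else {
    stop("panel CSV must be long form (respondent_id, attribute, mir) ",
         "or wide form (mir_<attribute> columns)")
  }
  validate_panel(df)
  df <- df[, c("respondent_id", "age_group", "attribute", "mir",
               "censored", "straight_liner")]
  rownames(df) <- NULL
  df
}

validate_panel <- function(panel) {
  bad <- which(!is.na(panel$mir) & panel$mir <= 0)
  if (length(bad))
    stop("non-positive MIR at row(s) ", paste(bad, collapse = ", "),
         " (respondent ", panel$respondent_id[bad[1]], ", attribute ",
         panel$attribute[bad[1]], ")")
  known <- panel$age_group %in% c("under60", "ge60") | is.na(panel$age_group)
  if (!all(known))
    stop("unknown age_group value(s): ",
         paste(unique(panel$age_group[!known]), collapse = ", "))
  invisible(panel)
}

#' @rdname read_panel
#' @param panel a long-format panel data frame.
#' @param format `"long"` (default) or `"wide"`.
#' @export
write_panel <- function(panel, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    attrs <- unique(panel$attribute)
    ids <- unique(panel$respondent_id)
    wide <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
    meta <- unique(panel[, c("respondent_id", "age_group", "straight_liner")])
    wide$age_group <- meta$age_group[match(ids, meta$respondent_id)]
    wide$straight_liner <- meta$straight_liner[match(ids, meta$respondent_id)]
    for (a in attrs) {
      sub <- panel[panel$attribute == a, ]
      wide[[paste0("mir_", a)]] <- sub$mir[match(ids, sub$respondent_id)]
    }
    utils::write.csv(wide, path, row.names = FALSE)
  } else {
    utils::write.csv(panel, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write choice logs as CSV
#'
#' Columns: `respondent_id`, `attribute`, `iteration`, `offered_change`,
#' `chose_procedure` (0/1).
#'
#' @param path file path.
#' @return choice-log data frame with `chose_procedure` as logical.
#' @export
read_choice_logs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "attribute", "iteration", "offered_change",
            "chose_procedure")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("choice log missing column(s): ", paste(missing, collapse = ", "))
  df$chose_procedure <- as.logical(df$chose_procedure)
  df[, need]
}

#' @rdname read_choice_logs
#' @param logs choice-log data frame.
#' @export
write_choice_logs <- function(logs, path) {
  logs$chose_procedure <- as.integer(logs$chose_procedure)
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}

# polynomial rolling hash of a string, rendered as 8 hex digits; used to
# fingerprint configurations in result metadata (not cryptographic)
str_digest <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_digest <- function(config) {
  str_digest(as.character(
    jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)))
}

#' Run the full benefit-risk pipeline
#'
#' Executes every stage -- panel load or synthesis, per-group weights, value
#' decomposition, threshold analysis, Monte Carlo simulation -- and collects
#' the results in a single machine-readable list from which
#' [render_report()] can produce a human-readable report. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config a [bra_config()] or path to a config JSON.
#' @param panel a long-format panel data frame, path to a panel CSV, or a
#'   [panel_spec()] to synthesise one.
#' @param groups subgroups to analyse.
#' @param n_iterations,scheme,exclude_straight_liners Monte Carlo settings.
#' @param seed integer seed used for panel synthesis and the MCS.
#' @return list of class `bra_results` with elements `meta`, `panel_summary`,
#'   `weights`, `decomposition`, `thresholds`, `mcs` (the last four keyed by
#'   group).
#' @export
run_pipeline <- function(config, panel, groups = c("all", "under60", "ge60"),
                         n_iterations = 10000, seed = 1L,
                         scheme = "respondent",
                         exclude_straight_liners = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  config <- stage("config", {
    if (is.character(config)) read_bra_config(config) else validate_config(config)
  })
  panel <- stage("panel", {
    if (inherits(panel, "panel_spec")) generate_panel(panel, seed = seed)$panel
    else if (is.character(panel)) read_panel(panel)
    else panel
  })
  if (is.null(panel) || nrow(panel) == 0)
    stop("pipeline stage 'weights' failed: empty panel", call. = FALSE)
  impacts <- stage("impacts", impact_table(config))
  psummary <- stage("panel_summary",
                    panel_summary(panel, config$attributes, impacts,
                                  exclude_straight_liners = exclude_straight_liners))
  fits <- list(); mcs <- list()
  for (g in groups) {
    fits[[g]] <- stage(paste0("weights/", g),
                       bra(config, panel = panel, group = g,
                           exclude_straight_liners = exclude_straight_liners))
    mcs[[g]] <- stage(paste0("mcs/", g),
                      run_mcs(config, panel, n_iterations = n_iterations,
                              seed = seed + match(g, groups) - 1L,
                              scheme = scheme, group = g,
                              exclude_straight_liners = exclude_straight_liners))
  }
  structure(list(
    meta = list(seed = seed, n_iterations = n_iterations, scheme = scheme,
                exclude_straight_liners = exclude_straight_liners,
                groups = groups, config_digest = config_digest(config),
                n_respondents = length(unique(panel$respondent_id))),
    attributes = config$attributes,
    impacts = as.list(impacts),
    panel_summary = psummary,
    weights = lapply(fits, function(f)
      list(raw = as.list(f$weights$raw),
           normalized = as.list(f$weights$normalized))),
    decomposition = lapply(fits, function(f)
      list(overall = f$decomposition$overall_increment,
           per_attribute = as.list(f$decomposition$per_attribute))),
    thresholds = lapply(fits, function(f) f$thresholds),
    mcs = lapply(mcs, function(m)
      list(p_first = as.list(m$p_first), mc_se = as.list(m$mc_se),
           n_iterations = m$n_iterations, seed = m$seed, scheme = m$scheme,
           subgroup = m$subgroup, exclusions = m$exclusions))
  ), class = "bra_results")
}

fmt_level <- function(x, units, digits = 1) {
  ifelse(units == "proportion", sprintf(paste0("%.", digits, "f%%"), 100 * x),
         ifelse(units == "years", sprintf(paste0("%.", digits, "f yrs"), x),
                sprintf("%.3g", x)))
}

#' Render a pipeline report
#'
#' A pure renderer: every number in the markdown report comes from the
#' results object alone.
#'
#' @param results a `bra_results` list from [run_pipeline()].
#' @return character scalar of markdown.
#' @export
render_report <- function(results) {
  attrs <- results$attributes
  units_of <- function(a) attrs$units[match(a, attrs$name)]
  lines <- c(
    "# Benefit-risk analysis report", "",
    sprintf("seed: %d | MCS iterations: %d | scheme: %s | config: %s | respondents: %d",
            results$meta$seed, results$meta$n_iterations, results$meta$scheme,
            results$meta$config_digest, results$meta$n_respondents), "",
    "## Panel summary (MIR/MRB by attribute and group)", "",
    "| attribute | group | mean | sd | n | % MIR > impact |",
    "|---|---|---|---|---|---|")
  ps <- results$panel_summary
  for (i in seq_len(nrow(ps))) {
    u <- units_of(ps$attribute[i])
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %d | %s |",
      ps$attribute[i], ps$group[i],
      fmt_level(ps$mean[i], u, 2), fmt_level(ps$sd[i], u, 2), ps$n[i],
      if (is.null(ps$prop_mir_gt_impact)) "" else
        sprintf("%.1f%%", ps$prop_mir_gt_impact[i])))
  }
  lines <- c(lines, "", "## Threshold analysis", "",
             paste0("| attribute | kind | ",
                    paste(names(results$thresholds), collapse = " | "), " |"),
             paste0("|---|---|", paste(rep("---|", length(results$thresholds)),
                                       collapse = "")))
  first <- results$thresholds[[1]]
  for (i in seq_len(nrow(first))) {
    u <- units_of(first$attribute[i])
    cells <- vapply(results$thresholds, function(tt)
      fmt_level(tt$threshold[i], u), character(1))
    lines <- c(lines, sprintf("| %s | %s | %s |", first$attribute[i],
                              first$kind[i], paste(cells, collapse = " | ")))
  }
  lines <- c(lines, "", "## Monte Carlo simulation", "",
             "| group | alternative | P(first) | MC SE |", "|---|---|---|---|")
  for (g in names(results$mcs)) {
    m <- results$mcs[[g]]
    for (alt in names(m$p_first))
      lines <- c(lines, sprintf("| %s | %s | %.1f%% | %.2f%% |", g, alt,
                                100 * m$p_first[[alt]], 100 * m$mc_se[[alt]]))
  }
  paste(lines, collapse = "\n")
}

#' Write pipeline results to disk
#'
#' Writes `results.json` (machine-readable) and `report.md` (rendered via
#' [render_report()]).
#'
#' @param results a `bra_results` list.
#' @param dir output directory, created if needed.
#' @return named character vector of written paths (the file manifest).
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(unclass(results), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  report_path <- file.path(dir, "report.md")
  writeLines(render_report(results), report_path)
  c(results = json_path, report = report_path)
}
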