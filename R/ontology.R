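#' Load a chemotherapy agent ontology
#'
#' The ontology names the canonical agents, groups them into drug classes
#' (one class per cytotoxic agent; a `steroid` class holding the
#' prednisone family, with dexamethasone as a separate steroid-class
#' member used only where a template names it), designates the
#' pre-specified `screen_agents` used by the step-1 billing filter, and
#' carries a case-insensitive synonym map for billing-dialect agent names.
#'
#' The shipped default lists the twelve agents named across the standard
#' B-NHL regimens (cyclophosphamide, vincristine, doxorubicin,
#' methotrexate, prednisone, prednisolone, methylprednisolone, rituximab,
#' etoposide, ifosfamide, cytarabine, dexamethasone); the screen-agent
#' list is configurable so institutions can extend it.
#'
#' @param path YAML config path; defaults to the shipped ontology.
#' @return An object of class `bnhl_ontology`: a list with elements
#'   `agents`, `classes`, `steroid_classes`, `screen_agents`, `synonyms`.
#' @export
load_ontology <- function(path = system.file("extdata", "ontology.yaml",
                                             package = "bnhlphenotype")) {
  if (!file.exists(path)) stop("ontology config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("agents", "classes", "screen_agents"))
    if (is.null(cfg[[field]]))
      stop("ontology config missing required field: ", field)
  agents <- tolower(unlist(cfg$agents))
  classes <- lapply(cfg$classes, function(a) tolower(unlist(a)))
  for (cl in names(classes)) {
    unknown <- setdiff(classes[[cl]], agents)
    if (length(unknown))
      stop(sprintf("class '%s' names agent(s) absent from the agent list: %s",
                   cl, paste(unknown, collapse = ", ")))
  }
  if (!"steroid" %in% names(classes))
    stop("ontology config must define a 'steroid' class")
  need <- c("prednisone", "prednisolone", "methylprednisolone")
  if (!all(need %in% classes$steroid))
    stop("the steroid class must contain at least: ",
         paste(setdiff(need, classes$steroid), collapse = ", "))
  screen <- tolower(unlist(cfg$screen_agents))
  unknown <- setdiff(screen, agents)
  if (length(unknown))
    stop("screen_agents absent from the agent list: ",
         paste(unknown, collapse = ", "))
  steroid_classes <- if (is.null(cfg$steroid_classes)) "steroid"
                     else intersect(unlist(cfg$steroid_classes),
                                    names(classes))
  synonyms <- if (is.null(cfg$synonyms)) character(0)
              else vapply(cfg$synonyms, function(x) tolower(x), character(1))
  names(synonyms) <- tolower(names(synonyms))
  bad <- setdiff(unname(synonyms), agents)
  if (length(bad))
    stop("synonym target(s) absent from the agent list: ",
         paste(bad, collapse = ", "))
  structure(list(agents = agents, classes = classes,
                 steroid_classes = steroid_classes,
                 screen_agents = screen, synonyms = synonyms),
            class = "bnhl_ontology")
}

#' @export
print.bnhl_ontology <- function(x, ...) {
  cat("<bnhl_ontology>\n")
  cat(sprintf("  %d agents, %d classes, %d screen agents\n",
              length(x$agents), length(x$classes), length(x$screen_agents)))
  cat("  steroid classes:", paste(x$steroid_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Canonicalise agent names
#'
#' Lower-cases, trims, and resolves billing-dialect synonyms. Unknown
#' agents raise an error: drug bills must name agents from the configured
#' ontology.
#'
#' @param x character vector of agent names as billed.
#' @param ontology a `bnhl_ontology`.
#' @return character vector of canonical agent names.
#' @export
canonical_agent <- function(x, ontology) {
  y <- tolower(trimws(x))
  hit <- y %in% names(ontology$synonyms)
  y[hit] <- unname(ontology$synonyms[y[hit]])
  unknown <- setdiff(unique(y), ontology$agents)
  if (length(unknown))
    stop("agent(s) not in the configured ontology: ",
         paste(unknown, collapse = ", "))
  y
}

# named vector: canonical agent -> class name (NA_character_ if unclassed)
agent_class_map <- function(ontology) {
  m <- rep(NA_character_, length(ontology$agents))
  names(m) <- ontology$agents
  for (cl in names(ontology$classes)) m[ontology$classes[[cl]]] <- cl
  m
}

#' Load regimen cycle templates
#'
#' Each template is a named cycle blueprint: required drug classes with
#' canonical day offsets inside the cycle (day 0 = first administered
#' agent), an optional flag per class, and the cycle span. The shipped
#' defaults encode the seven standard B-NHL cycles (COP, COPADM, RCOPADM,
#' COPAD, REPOCH, BFM95_C1, BFM95_C2); see the packaged `regimens.yaml`
#' for the compositions. Canonical offsets place every class within a
#' 5-day window; the matcher's tolerance rules absorb schedule detail, and
#' users can override the config with trial-accurate schedules.
#'
#' @param path YAML config path; defaults to the shipped templates.
#' @param ontology a `bnhl_ontology` used to validate class references.
#' @return An object of class `bnhl_templates`: a named list of templates,
#'   each a list with `name`, `cycle_span_days` and a `classes` data.frame
#'   (`class`, `offset`, `optional`), plus a `later_course` attribute
#'   naming templates that trigger the 60-day lookback.
#' @export
load_templates <- function(path = system.file("extdata", "regimens.yaml",
                                              package = "bnhlphenotype"),
                           ontology = load_ontology()) {
  if (!file.exists(path)) stop("regimen config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$templates)) stop("regimen config missing 'templates'")
  out <- lapply(names(cfg$templates), function(nm) {
    t <- cfg$templates[[nm]]
    span <- as.integer(t$cycle_span_days)
    cls <- do.call(rbind, lapply(t$classes, function(c) {
      data.frame(class = c$class, offset = as.integer(c$offset),
                 optional = isTRUE(c$optional),
                 distinguishing = isTRUE(c$distinguishing),
                 stringsAsFactors = FALSE)
    }))
    unknown <- setdiff(cls$class, names(ontology$classes))
    if (length(unknown))
      stop(sprintf("template '%s' references unknown class(es): %s",
                   nm, paste(unknown, collapse = ", ")))
    if (all(cls$optional))
      stop(sprintf("template '%s' must have at least one non-optional class",
                   nm))
    if (any(cls$offset < 0L | cls$offset >= span))
      stop(sprintf("template '%s' has day offsets outside [0, %d)", nm, span))
    list(name = nm, cycle_span_days = span, classes = cls)
  })
  names(out) <- names(cfg$templates)
  later <- intersect(unlist(cfg$later_course_templates), names(out))
  structure(out, later_course = later, class = "bnhl_templates")
}

#' @export
print.bnhl_templates <- function(x, ...) {
  cat("<bnhl_templates>\n")
  for (t in x) {
    req <- t$classes$class[!t$classes$optional]
    opt <- t$classes$class[t$classes$optional]
    cat(sprintf("  %-9s %s%s\n", t$name, paste(req, collapse = "+"),
                if (length(opt)) paste0(" (+/- ", paste(opt, collapse = "+"),
                                        ")") else ""))
  }
  invisible(x)
}

#' Load the B-NHL diagnosis-code table
#'
#' The shipped default is the standard screening list: ICD-9 prefixes
#' 200.0, 200.2, 200.5, 200.7, 200.8, 202.8, 202.9 and their ICD-10
#' analogues (C83.3/7/8/9, C85.1/2/8/9, C96.9, C96.Z). Codes are matched
#' by prefix, so an entry `200.2` matches any billed code beginning
#' `200.2`.
#'
#' @param path CSV path with columns `code_system`, `code_prefix`,
#'   `description`.
#' @return data.frame of code prefixes.
#' @export
load_codes <- function(path = system.file("extdata", "codes.csv",
                                          package = "bnhlphenotype")) {
  df <- read_table_checked(path, c("code_system", "code_prefix"))
  bad <- !df$code_system %in% c("ICD9", "ICD10")
  if (any(bad))
    stop("codes table: unknown code_system at data row ", which(bad)[1])
  df
}
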