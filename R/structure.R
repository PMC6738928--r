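# Conceptual model structure: the accepted health events, patient attributes
# and attribute->event dependency edges that define the simulation state space.

#' Define a health event
#'
#' @param name event name.
#' @param kind `"recurrent"` (may occur in multiple cycles) or `"absorbing"`
#'   (terminal; death).
#' @param persistent logical; once the event occurs the individual stays in
#'   that state (a persistent binary state short of death, e.g. residential
#'   care admission).
#' @param history_counter optional name of a count attribute incremented each
#'   time the event occurs (e.g. `previous_fractures`).
#' @return list of class `health_event`.
#' @export
health_event <- function(name, kind = c("recurrent", "absorbing"),
                         persistent = FALSE, history_counter = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), nchar(name) > 0, is.logical(persistent))
  structure(list(name = name, kind = kind, persistent = persistent,
                 history_counter = history_counter),
            class = "health_event")
}

#' Define a patient attribute
#'
#' @param name attribute name.
#' @param value_type one of `"continuous"`, `"binary"`, `"count"`,
#'   `"categorical"`.
#' @param time_varying logical; whether the simulation may update the value
#'   between cycles (history counters must be time-varying counts).
#' @return list of class `patient_attribute`.
#' @export
patient_attribute <- function(name, value_type = c("continuous", "binary", "count", "categorical"),
                              time_varying = FALSE) {
  value_type <- match.arg(value_type)
  structure(list(name = name, value_type = value_type, time_varying = time_varying),
            class = "patient_attribute")
}

#' Assemble a model structure
#'
#' @param events list of [health_event()] objects.
#' @param attributes list of [patient_attribute()] objects.
#' @param edges data frame with columns `attribute`, `event`, the dependency
#'   edges (which attributes feed which event's risk equation).
#' @return object of class `frail_structure`.
#' @export
model_structure <- function(events, attributes, edges = NULL) {
  ev_names <- vapply(events, `[[`, character(1), "name")
  at_names <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(ev_names)) stop("duplicate event names", call. = FALSE)
  if (anyDuplicated(at_names)) stop("duplicate attribute names", call. = FALSE)
  if (length(intersect(ev_names, at_names)))
    stop("a name cannot be both an event and an attribute", call. = FALSE)
  absorbing <- vapply(events, function(e) e$kind == "absorbing", logical(1))
  if (sum(absorbing) > 1) stop("at most one absorbing event (death)", call. = FALSE)
  counters <- stats::na.omit(vapply(events, `[[`, character(1), "history_counter"))
  bad <- setdiff(counters, at_names)
  if (length(bad))
    stop("history counters missing from attributes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(edges)) edges <- data.frame(attribute = character(), event = character())
  stopifnot(all(c("attribute", "event") %in% names(edges)))
  structure(list(events = events, attributes = attributes,
                 edges = edges[, c("attribute", "event"), drop = FALSE]),
            class = "frail_structure")
}

event_names <- function(structure) vapply(structure$events, `[[`, character(1), "name")
attribute_names <- function(structure) vapply(structure$attributes, `[[`, character(1), "name")

absorbing_event <- function(structure) {
  abs <- Filter(function(e) e$kind == "absorbing", structure$events)
  if (length(abs) == 0) return(NULL)
  abs[[1]]$name
}

nonfatal_events <- function(structure) {
  Filter(function(e) e$kind != "absorbing", structure$events)
}

counter_attributes <- function(structure) {
  unique(stats::na.omit(vapply(structure$events, `[[`, character(1), "history_counter")))
}

persistent_events <- function(structure) {
  vapply(Filter(function(e) isTRUE(e$persistent), structure$events), `[[`,
         character(1), "name")
}

#' The default (consensus) frailty model structure
#'
#' Seven health events — hip fracture, falls, residential care admission,
#' hospital admission, physical disability, delirium and death — and eleven
#' patient attributes: age, gender, level of education, frailty status,
#' number of previous hospital admissions, number of previous fractures,
#' polypharmacy, stroke, diabetes, level of physical activity and depression.
#' Hip fracture and hospital admission increment history counters;
#' residential care admission and physical disability are persistent binary
#' states; death is the absorbing state. Depression appears as a
#' (time-varying) patient attribute only. Default edges wire age, gender and
#' frailty status into every event, plus the event-specific history counters.
#'
#' @return a `frail_structure`.
#' @export
default_structure <- function() {
  events <- list(
    health_event("hip_fracture", "recurrent", history_counter = "previous_fractures"),
    health_event("falls", "recurrent"),
    health_event("residential_care", "recurrent", persistent = TRUE),
    health_event("hospital_admission", "recurrent",
                 history_counter = "previous_hospital_admissions"),
    health_event("physical_disability", "recurrent", persistent = TRUE),
    health_event("delirium", "recurrent"),
    health_event("death", "absorbing")
  )
  attributes <- list(
    patient_attribute("age", "continuous", time_varying = TRUE),
    patient_attribute("gender", "binary"),
    patient_attribute("education", "categorical"),
    patient_attribute("frailty_status", "categorical", time_varying = TRUE),
    patient_attribute("previous_hospital_admissions", "count", time_varying = TRUE),
    patient_attribute("previous_fractures", "count", time_varying = TRUE),
    patient_attribute("polypharmacy", "binary"),
    patient_attribute("stroke", "binary"),
    patient_attribute("diabetes", "binary"),
    patient_attribute("physical_activity", "binary"),
    patient_attribute("depression", "binary", time_varying = TRUE)
  )
  ev <- vapply(events, `[[`, character(1), "name")
  edges <- data.frame(
    attribute = c(rep(c("age", "gender", "frailty_status"), each = length(ev)),
                  "previous_fractures", "previous_hospital_admissions"),
    event = c(rep(ev, 3), "hip_fracture", "hospital_admission"))
  model_structure(events, attributes, edges)
}

# conventional semantics attached to known event names when building a
# structure from Delphi outcomes
known_event_traits <- function(name) {
  switch(name,
         death = list(kind = "absorbing", persistent = FALSE, counter = NA_character_),
         hip_fracture = list(kind = "recurrent", persistent = FALSE,
                             counter = "previous_fractures"),
         hospital_admission = list(kind = "recurrent", persistent = FALSE,
                                   counter = "previous_hospital_admissions"),
         residential_care = list(kind = "recurrent", persistent = TRUE,
                                 counter = NA_character_),
         physical_disability = list(kind = "recurrent", persistent = TRUE,
                                    counter = NA_character_),
         list(kind = "recurrent", persistent = FALSE, counter = NA_character_))
}

known_attribute_traits <- function(name) {
  switch(name,
         age = list(value_type = "continuous", time_varying = TRUE),
         frailty_status = list(value_type = "categorical", time_varying = TRUE),
         previous_hospital_admissions = ,
         previous_fractures = list(value_type = "count", time_varying = TRUE),
         education = list(value_type = "categorical", time_varying = FALSE),
         depression = list(value_type = "binary", time_varying = TRUE),
         list(value_type = "binary", time_varying = FALSE))
}

#' Build a model structure from Delphi classification outcomes
#'
#' Keeps exactly the choices whose final decision is `included` (directly or
#' after round 3). Death is always added (with a warning) when absent, since
#' a lifetime-horizon model needs an absorbing state. Known event names get
#' their conventional semantics (history counters, persistence); counters are
#' added as attributes when needed. Output is invariant to input ordering.
#'
#' @param classifications the report data frame from
#'   [classify_delphi_responses()], or a list of `delphi_classification`
#'   objects.
#' @return a `frail_structure`.
#' @export
build_from_classifications <- function(classifications) {
  if (is.data.frame(classifications)) {
    df <- classifications
  } else {
    df <- do.call(rbind, lapply(classifications, function(cl) {
      data.frame(choice_name = cl$choice_name, choice_kind = cl$choice_kind,
                 final = final_decision(cl), stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(choice_name = character(),
                                      choice_kind = character(), final = character())
  }
  if (anyDuplicated(df$choice_name))
    stop("duplicate choice names in classifications", call. = FALSE)
  if (nrow(df) && any(df$final == "round3"))
    stop("classifications incomplete: some choices still await round 3", call. = FALSE)
  keep <- df[df$final == "included", , drop = FALSE]
  keep <- keep[order(keep$choice_name), , drop = FALSE]
  ev_names <- keep$choice_name[keep$choice_kind == "health_event"]
  at_names <- keep$choice_name[keep$choice_kind == "patient_attribute"]
  if (!"death" %in% ev_names) {
    warning("no absorbing death event among included choices; adding one")
    ev_names <- c(ev_names, "death")
  }
  events <- lapply(ev_names, function(nm) {
    tr <- known_event_traits(nm)
    health_event(nm, tr$kind, tr$persistent, tr$counter)
  })
  counters <- unique(stats::na.omit(vapply(events, `[[`, character(1), "history_counter")))
  at_names <- union(at_names, counters)
  attributes <- lapply(sort(at_names), function(nm) {
    tr <- known_attribute_traits(nm)
    patient_attribute(nm, tr$value_type, tr$time_varying)
  })
  core <- intersect(c("age", "gender", "frailty_status"), at_names)
  edges <- if (length(core)) {
    data.frame(attribute = rep(core, each = length(ev_names)),
               event = rep(ev_names, length(core)))
  } else {
    data.frame(attribute = character(), event = character())
  }
  for (e in events) {
    if (!is.na(e$history_counter))
      edges <- rbind(edges, data.frame(attribute = e$history_counter, event = e$name))
  }
  model_structure(events, attributes, edges)
}

#' Diagnose structural problems
#'
#' Reports (as character findings, not errors): a missing absorbing death
#' state, orphan events with no incoming dependency edge, and dangling edges
#' whose endpoints are not part of the structure. An empty return means the
#' structure is well formed.
#'
#' @param structure a `frail_structure`.
#' @return character vector of findings (zero length when clean).
#' @export
validate_structure <- function(structure) {
  stopifnot(inherits(structure, "frail_structure"))
  findings <- character()
  if (is.null(absorbing_event(structure)))
    findings <- c(findings, "no absorbing state: structure lacks a death event")
  ev <- event_names(structure)
  at <- attribute_names(structure)
  edges <- structure$edges
  dangling <- !(edges$attribute %in% at) | !(edges$event %in% ev)
  if (any(dangling))
    findings <- c(findings, paste0("dangling edge: ", edges$attribute[dangling],
                                   " -> ", edges$event[dangling]))
  orphan <- setdiff(ev, unique(edges$event[!dangling]))
  if (length(orphan))
    findings <- c(findings, paste0("orphan event (no predictors): ", orphan))
  findings
}

#' @export
print.frail_structure <- function(x, ...) {
  cat(sprintf("<frail_structure> %d events, %d attributes, %d edges\n",
              length(x$events), length(x$attributes), nrow(x$edges)))
  cat("  events:", paste(event_names(x), collapse = ", "), "\n")
  cat("  attributes:", paste(attribute_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a model structure to JSON
#'
#' @param structure a `frail_structure`.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
write_structure <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "frail_structure"))
  payload <- list(
    events = lapply(structure$events, function(e)
      list(name = e$name, kind = e$kind, persistent = e$persistent,
           history_counter = e$history_counter)),
    attributes = lapply(structure$attributes, function(a)
      list(name = a$name, value_type = a$value_type, time_varying = a$time_varying)),
    edges = structure$edges)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a model structure from JSON
#'
#' @param path file path or a JSON string produced by [write_structure()].
#' @return a `frail_structure`.
#' @export
read_structure <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  events <- lapply(payload$events, function(e)
    health_event(e$name, e$kind, isTRUE(e$persistent),
                 if (is.null(e$history_counter)) NA_character_ else e$history_counter))
  attributes <- lapply(payload$attributes, function(a)
    patient_attribute(a$name, a$value_type, isTRUE(a$time_varying)))
  edges <- if (length(payload$edges)) {
    do.call(rbind, lapply(payload$edges, function(e)
      data.frame(attribute = e$attribute, event = e$event)))
  } else NULL
  model_structure(events, attributes, edges)
}
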