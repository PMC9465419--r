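#' Construct a hierarchical REO panel
#'
#' A panel is an ordered list of binary gene-pair signatures arranged as a
#' decision tree. Each step routes its positive and negative outcome either to
#' a terminal subtype label (`"label:<name>"`) or to another step
#' (`"step:<index>"`). The built-in diagnostic panel routes:
#' NE-signature negative -> non-NE; positive -> CARCI-signature;
#' CARCI positive -> CARCI; negative -> SCLC-signature;
#' SCLC positive -> SCLC; negative -> LCNEC.
#'
#' @param steps List of [reo_signature] objects.
#' @param routing List (same length as `steps`) of lists with elements
#'   `on_positive` and `on_negative`, each `"label:<terminal>"` or
#'   `"step:<i>"`.
#' @param name Panel name.
#' @param terminal_labels Character vector of allowed terminal labels.
#' @return Object of class `reo_panel`.
#' @export
reo_panel <- function(steps, routing, name = "REO panel",
                      terminal_labels = NULL) {
  if (length(steps) == 0L) stop("panel needs at least one signature step")
  if (length(routing) != length(steps)) {
    stop("routing must have one entry per step")
  }
  lapply(steps, validate_signature)
  if (is.null(terminal_labels)) {
    terminal_labels <- unique(unlist(lapply(routing, function(r) {
      tg <- c(r$on_positive, r$on_negative)
      sub("^label:", "", tg[startsWith(tg, "label:")])
    })))
  }
  panel <- structure(list(name = name, steps = steps, routing = routing,
                          terminal_labels = terminal_labels),
                     class = "reo_panel")
  validate_panel(panel)
  panel
}

parse_route <- function(x) {
  if (startsWith(x, "label:")) {
    list(type = "label", label = sub("^label:", "", x))
  } else if (startsWith(x, "step:")) {
    list(type = "step", step = as.integer(sub("^step:", "", x)))
  } else stop("malformed routing target '", x, "'")
}

validate_panel <- function(panel) {
  n <- length(panel$steps)
  seen <- rep(FALSE, n)
  # walk the tree from step 1; every route must hit a later step or a terminal
  walk <- function(i) {
    if (i < 1L || i > n) stop("routing points to nonexistent step ", i)
    if (seen[i]) stop("panel routing contains a cycle at step ", i)
    seen[i] <<- TRUE
    for (tgt in c(panel$routing[[i]]$on_positive, panel$routing[[i]]$on_negative)) {
      r <- parse_route(tgt)
      if (r$type == "step") {
        walk(r$step)
      } else if (!r$label %in% panel$terminal_labels) {
        stop("terminal label '", r$label, "' not in declared terminal set")
      }
    }
  }
  walk(1L)
  if (!all(seen)) {
    stop("unreachable panel step(s): ", paste(which(!seen), collapse = ", "))
  }
  invisible(panel)
}

#' @export
print.reo_panel <- function(x, ...) {
  cat("Hierarchical REO panel '", x$name, "': ", length(x$steps),
      " signature steps\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    r <- x$routing[[i]]
    cat(sprintf("  %d. %s (%d pairs): positive -> %s, negative -> %s\n",
                i, s$name, nrow(s$pairs),
                sub("^(label|step):", "\\1 ", r$on_positive),
                sub("^(label|step):", "\\1 ", r$on_negative)))
  }
  cat("terminal labels:", paste(x$terminal_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.reo_panel <- function(object, ...) {
  cat("Panel '", object$name, "'\n", sep = "")
  for (s in object$steps) {
    cat("\n")
    print(s)
  }
  if (!is.null(object$training)) {
    cat("\nTraining report:\n")
    for (nm in names(object$training$steps)) {
      tr <- object$training$steps[[nm]]
      cat(sprintf("  %s: apparent sensitivity %.2f, specificity %.2f (n = %d)\n",
                  nm, tr$sensitivity, tr$specificity, tr$n))
    }
  }
  invisible(object)
}

#' Load the built-in 92-pair lung NE diagnostic panel
#'
#' Returns the packaged hierarchical panel: a 22-pair NE-signature
#' (NE vs non-NE), a 30-pair CARCI-signature (carcinoid vs other NE) and a
#' 40-pair SCLC-signature (small-cell vs large-cell NE carcinoma), with genes
#' keyed by Entrez ID. The panel is validated on load; a corrupted resource
#' (wrong pair count or a duplicated gene within a signature) is an error.
#'
#' @return An `reo_panel` with three signature steps.
#' @examples
#' panel <- builtin_panel()
#' panel
#' @export
builtin_panel <- function() {
  path <- system.file("extdata", "nesubtype_panel.json", package = "reopanel",
                      mustWork = TRUE)
  panel <- read_panel_file(path)
  counts <- vapply(panel$steps, function(s) nrow(s$pairs), integer(1))
  if (!identical(counts, c(22L, 30L, 40L))) {
    stop("built-in panel resource corrupted: expected 22/30/40 pairs, got ",
         paste(counts, collapse = "/"))
  }
  panel
}

#' Read / write a panel as JSON
#'
#' @param path File path.
#' @return `read_panel_file` returns an `reo_panel`.
#' @export
read_panel_file <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- list()
  routing <- list()
  nsteps <- if (is.data.frame(raw$steps)) nrow(raw$steps) else length(raw$steps)
  for (i in seq_len(nsteps)) {
    s <- if (is.data.frame(raw$steps)) lapply(raw$steps, `[[`, i) else raw$steps[[i]]
    steps[[i]] <- reo_signature(as.data.frame(s$pairs, stringsAsFactors = FALSE),
                                name = s$name,
                                positive_label = s$positive_label,
                                negative_label = s$negative_label)
    routing[[i]] <- list(on_positive = s$on_positive, on_negative = s$on_negative)
  }
  reo_panel(steps, routing, name = raw$name,
            terminal_labels = unlist(raw$terminal_labels))
}

#' @rdname read_panel_file
#' @param panel An `reo_panel`.
#' @export
write_panel_file <- function(panel, path) {
  validate_panel(panel)
  out <- list(
    name = panel$name,
    terminal_labels = panel$terminal_labels,
    steps = lapply(seq_along(panel$steps), function(i) {
      s <- panel$steps[[i]]
      list(name = s$name, positive_label = s$positive_label,
           negative_label = s$negative_label,
           on_positive = panel$routing[[i]]$on_positive,
           on_negative = panel$routing[[i]]$on_negative,
           pairs = s$pairs)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
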