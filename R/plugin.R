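# Declarative plugin framework.  A plugin is a manifest: new entity kinds
# (with canonical id field and public attributes), associations binding them
# to core kinds, a data loader, and a test-suite callable.  Registration
# extends the kind/association registry of one dataset; core tables and core
# routes are untouched, so plugin-free and plugin-bearing services are
# byte-identical on every core-only route.

#' Declare a plugin
#'
#' @param name Plugin name (used for bookkeeping and logs).
#' @param types Named list; each element declares a kind:
#'   `list(plural =, id_field =, attributes =, sequence_bearing = FALSE)`.
#'   The element name is the kind name.
#' @param associations List of
#'   `list(kind =, name =, target_kind =, cardinality =, fetch = function(ds, entity))`,
#'   where `fetch` returns canonical identifier(s) of the target kind.
#' @param loader `function(dataset, source)` filling the plugin's tables from
#'   a data source; must skip-and-log rows that do not resolve against core
#'   entities.
#' @param tests `function(dataset)` returning a character vector of failure
#'   descriptions (empty when the plugin's own invariants hold); federated
#'   into `selftest`.
#' @return A `plugin_manifest`.
#' @export
plugin_manifest <- function(name, types, associations, loader, tests) {
  if (!nzchar(name)) mirkit_error("mirkit_bad_manifest", "plugin needs a name")
  if (!is.function(loader) || !is.function(tests))
    mirkit_error("mirkit_bad_manifest",
                 "plugin manifest needs loader and tests functions")
  structure(list(name = name, types = types, associations = associations,
                 loader = loader, tests = tests),
            class = "plugin_manifest")
}

#' Register a plugin with a dataset
#'
#' Checks that no declared kind, plural path segment or association collides
#' with the core or a previously registered plugin and that every association
#' endpoint names a registered kind; then extends the registry so plugin
#' kinds are queryable via [get_entity()] / [traverse()] and resolvable and
#' listed by the resource layer.
#'
#' @param dataset A `mir_dataset` (mutated in place).
#' @param manifest A [plugin_manifest()].
#' @return The dataset, invisibly.
#' @export
register_plugin <- function(dataset, manifest) {
  if (!inherits(manifest, "plugin_manifest"))
    mirkit_error("mirkit_bad_manifest", "not a plugin_manifest")
  if (manifest$name %in% names(dataset$plugins))
    mirkit_error("mirkit_plugin_collision",
                 sprintf("plugin '%s' already registered", manifest$name))
  plurals <- vapply(dataset$kinds, `[[`, "", "plural")
  for (kind in names(manifest$types)) {
    t <- manifest$types[[kind]]
    if (kind %in% names(dataset$kinds))
      mirkit_error("mirkit_plugin_collision",
                   sprintf("kind '%s' collides with a registered kind", kind))
    if (t$plural %in% plurals)
      mirkit_error("mirkit_plugin_collision",
                   sprintf("path segment '%s' collides with a registered route",
                           t$plural))
  }
  all_kinds <- c(names(dataset$kinds), names(manifest$types))
  for (a in manifest$associations) {
    if (!a$kind %in% all_kinds || !a$target_kind %in% all_kinds)
      mirkit_error("mirkit_plugin_dangling", sprintf(
        "association %s.%s references unregistered kind", a$kind, a$name))
    if (!is.null(dataset$associations[[assoc_key(a$kind, a$name)]]))
      mirkit_error("mirkit_plugin_collision", sprintf(
        "association '%s' already declared for kind '%s'", a$name, a$kind))
  }

  for (kind in names(manifest$types)) {
    t <- manifest$types[[kind]]
    dataset$kinds[[kind]] <- list(
      plural = t$plural, id_field = t$id_field, attributes = t$attributes,
      sequence_bearing = isTRUE(t$sequence_bearing), plugin = manifest$name)
    cols <- stats::setNames(rep(list(empty_chr), length(t$attributes)),
                            t$attributes)
    dataset$tab[[kind]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  for (a in manifest$associations) {
    a$plugin <- manifest$name
    dataset$associations[[assoc_key(a$kind, a$name)]] <- a
  }
  dataset$plugins[[manifest$name]] <- manifest
  mirkit_log("info", sprintf("registered plugin '%s'", manifest$name))
  invisible(dataset)
}

#' Load a registered plugin's data
#'
#' @param dataset A `mir_dataset`.
#' @param plugin Plugin name or `plugin_manifest`.
#' @param source Path (or whatever the plugin's loader accepts).
#' @return The dataset, invisibly.
#' @export
load_plugin_data <- function(dataset, plugin, source) {
  name <- if (inherits(plugin, "plugin_manifest")) plugin$name else plugin
  manifest <- dataset$plugins[[name]]
  if (is.null(manifest))
    mirkit_error("mirkit_not_found", sprintf("plugin '%s' is not registered", name))
  if (is.character(source) && !file.exists(source) && !dir.exists(source))
    mirkit_error("mirkit_source_missing", sprintf("no such source: %s", source))
  manifest$loader(dataset, source)
  invisible(dataset)
}

#' Run the test suites of all registered plugins
#'
#' @param dataset A `mir_dataset`.
#' @return Named list (one element per plugin) of character vectors of
#'   failure descriptions; all empty when every plugin invariant holds.
#' @export
run_plugin_tests <- function(dataset) {
  lapply(dataset$plugins, function(m) as.character(m$tests(dataset)))
}
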