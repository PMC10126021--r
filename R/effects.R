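#' Effect specifications
#'
#' An effect specification names one statistic column of the design array:
#' the covariate x_p(s, r, c, t) whose coefficient beta_p enters the
#' log-linear event rate. Exogenous effects (indicators, trait summaries)
#' are never standardized per event; endogenous effects (inertia, shared
#' partners and their setting-specific variants) are standardized per time
#' point by default (sample SD over the risk set, see [scale_per_event()]).
#'
#' Canonical names follow field conventions: `both.male`, `mixed.gender`,
#' `both.older`, `mixed.age`, `extraversion.min`, `extraversion.max`,
#' `inertia`, `shared.partners`, `weekend`, `group`, `study` (type dummy),
#' `setting.inertia`, `setting.shared.partners`, and `a.x.b` for
#' interactions.
#'
#' @param name Optional explicit effect name; a canonical name is derived
#'   when omitted.
#' @return A `rem_effect` object.
#' @name rem_effects
NULL

new_effect <- function(kind, name, scale = FALSE, params = list()) {
  structure(
    list(kind = kind, name = name, scale = scale, params = params),
    class = "rem_effect"
  )
}

#' @rdname rem_effects
#' @export
effect_baseline <- function(name = "baseline") {
  new_effect("baseline", name)
}

#' @rdname rem_effects
#' @param attribute Categorical actor attribute (e.g. `"gender"`,
#'   `"age_group"`).
#' @param mode For [effect_category_pair()]: `"both_level"` (1 iff both
#'   members have `level`) or `"mixed"` (1 iff the members differ on the
#'   attribute). For [effect_trait_extreme()]: `"min"` or `"max"`.
#' @param level Attribute level for `mode = "both_level"`.
#' @export
effect_category_pair <- function(attribute, mode = c("both_level", "mixed"),
                                 level = NULL, name = NULL) {
  mode <- match.arg(mode)
  if (mode == "both_level" && is.null(level)) {
    abort("mode 'both_level' requires a level")
  }
  if (is.null(name)) {
    name <- if (mode == "both_level") {
      paste0("both.", level)
    } else {
      paste0("mixed.", sub("_group$", "", attribute))
    }
  }
  new_effect("category_pair", name,
    params = list(attribute = attribute, mode = mode, level = level)
  )
}

#' @rdname rem_effects
#' @param trait Name of a standardized trait column in the actor table.
#' @export
effect_trait_extreme <- function(trait, mode = c("min", "max"), name = NULL) {
  mode <- match.arg(mode)
  name <- name %||% paste(trait, mode, sep = ".")
  new_effect(paste0("trait_", mode), name,
    params = list(trait = trait, mode = mode)
  )
}

#' @rdname rem_effects
#' @export
effect_weekend <- function(name = "weekend") {
  new_effect("weekend", name)
}

#' @rdname rem_effects
#' @export
effect_group <- function(name = "group") {
  new_effect("group", name)
}

#' @rdname rem_effects
#' @param scale Standardize this statistic per time point? Defaults to
#'   `TRUE` for endogenous effects.
#' @param weighted Use the duration- and group-size-weighted inertia
#'   (weight `ln(d_e) / (|A_e| - 1)` per past event)? `FALSE` counts each
#'   past event with weight 1 (the conventional measure).
#' @export
effect_inertia <- function(scale = TRUE, weighted = TRUE, name = "inertia") {
  new_effect("inertia", name, scale = scale, params = list(weighted = weighted))
}

#' @rdname rem_effects
#' @export
effect_shared_partners <- function(scale = TRUE, name = "shared.partners") {
  new_effect("shared_partners", name, scale = scale)
}

#' @rdname rem_effects
#' @param focal_type Event type whose indicator is 1 (e.g. `"study"`).
#' @export
effect_type_dummy <- function(focal_type, name = NULL) {
  new_effect("type_dummy", name %||% focal_type,
    params = list(focal_type = focal_type)
  )
}

#' @rdname rem_effects
#' @export
effect_type_inertia <- function(scale = TRUE, weighted = TRUE,
                                name = "setting.inertia") {
  new_effect("type_inertia", name,
    scale = scale,
    params = list(weighted = weighted)
  )
}

#' @rdname rem_effects
#' @export
effect_type_shared_partners <- function(scale = TRUE,
                                        name = "setting.shared.partners") {
  new_effect("type_shared_partners", name, scale = scale)
}

#' @rdname rem_effects
#' @param a,b Names of two previously defined effects whose columns are
#'   multiplied elementwise. Endogenous components are scaled before the
#'   product is taken; the product itself is not re-standardized.
#' @export
effect_interaction <- function(a, b, name = NULL) {
  new_effect("interaction", name %||% paste(a, b, sep = ".x."),
    params = list(a = a, b = b)
  )
}

#' Collect effect specifications into a validated list
#'
#' @param ... `rem_effect` objects (or a single list of them).
#' @return A named list of effects (class `rem_effect_list`).
#' @examples
#' effects(effect_baseline(), effect_inertia())
#' @export
effects <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) &&
    !inherits(specs[[1]], "rem_effect")) {
    specs <- specs[[1]]
  }
  ok <- vapply(specs, inherits, logical(1), "rem_effect")
  if (!all(ok)) {
    abort("all arguments must be rem_effect objects")
  }
  nm <- vapply(specs, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    abort(paste0("duplicate effect name(s): ", paste(dup, collapse = ", ")))
  }
  names(specs) <- nm
  for (sp in specs) {
    if (sp$kind == "interaction") {
      comp <- c(sp$params$a, sp$params$b)
      missing_comp <- setdiff(comp, nm)
      if (length(missing_comp)) {
        abort(paste0(
          "interaction '", sp$name, "' references undefined effect(s): ",
          paste(missing_comp, collapse = ", ")
        ))
      }
      if (any(vapply(specs[comp], `[[`, "", "kind") == "interaction")) {
        abort("interactions of interactions are not supported")
      }
    }
  }
  structure(specs, class = "rem_effect_list")
}

# build one effect from a config-file entry (a named list)
effect_from_config <- function(entry) {
  kind <- entry$kind
  if (is.null(kind)) {
    abort("every effect entry needs a 'kind'")
  }
  switch(kind,
    baseline = effect_baseline(name = entry$name %||% "baseline"),
    category_pair = effect_category_pair(
      entry$attribute,
      mode = entry$mode %||% "both_level",
      level = entry$level, name = entry$name
    ),
    trait_min = effect_trait_extreme(entry$trait, "min", name = entry$name),
    trait_max = effect_trait_extreme(entry$trait, "max", name = entry$name),
    weekend = effect_weekend(name = entry$name %||% "weekend"),
    group = effect_group(name = entry$name %||% "group"),
    inertia = effect_inertia(
      scale = entry$scale %||% TRUE, weighted = entry$weighted %||% TRUE,
      name = entry$name %||% "inertia"
    ),
    shared_partners = effect_shared_partners(
      scale = entry$scale %||% TRUE,
      name = entry$name %||% "shared.partners"
    ),
    type_dummy = effect_type_dummy(entry$focal_type, name = entry$name),
    type_inertia = effect_type_inertia(
      scale = entry$scale %||% TRUE, weighted = entry$weighted %||% TRUE,
      name = entry$name %||% "setting.inertia"
    ),
    type_shared_partners = effect_type_shared_partners(
      scale = entry$scale %||% TRUE,
      name = entry$name %||% "setting.shared.partners"
    ),
    interaction = effect_interaction(entry$a, entry$b, name = entry$name),
    abort(paste0("unknown effect kind: ", kind))
  )
}
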