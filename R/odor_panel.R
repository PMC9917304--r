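#' Odorant panels and stimulus metadata
#'
#' An odor panel is an ordered table of stimuli with the chemical descriptors
#' the analysis uses: functional group, carbon chain length and vapor
#' pressure. [aliphatic_panel()] returns the standard 16-odorant panel used in
#' honey bee olfaction work (4 functional groups x chain lengths C6-C9) plus
#' an unscented air control.
#'
#' Vapor pressures are literature values (mmHg at 25 degrees C) compiled from
#' standard physico-chemical reference tables; they are free parameters of the
#' analysis, not measurements, and can be overridden via the `vapor_pressure`
#' argument of [odor_panel()] or by editing the returned data frame.
#'
#' @param stimuli data frame with columns `name`, `functional_group`
#'   (`primary_alcohol`, `secondary_alcohol`, `aldehyde`, `ketone`,
#'   `pheromone` or `control`), `chain_length` (integer 6-9 or `NA`),
#'   `vapor_pressure` (mmHg or `NA`) and optionally `is_control`.
#' @param panel_name label for the panel.
#' @return An object of class `odor_panel`: a data frame with the columns
#'   above plus `is_control`.
#' @examples
#' p <- aliphatic_panel()
#' nrow(p)            # 17: 16 aliphatic odorants + air
#' table(p$functional_group)
#' @export
odor_panel <- function(stimuli, panel_name = "custom") {
  req <- c("name", "functional_group", "chain_length", "vapor_pressure")
  missing_cols <- setdiff(req, names(stimuli))
  if (length(missing_cols))
    stop("panel lacks columns: ", paste(missing_cols, collapse = ", "))
  groups <- c("primary_alcohol", "secondary_alcohol", "aldehyde", "ketone",
              "pheromone", "control")
  bad <- setdiff(unique(stimuli$functional_group), groups)
  if (length(bad))
    stop("unknown functional group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(stimuli$name))
    stop("stimulus names must be unique")
  if (is.null(stimuli$is_control))
    stimuli$is_control <- stimuli$functional_group == "control"
  if (any(stimuli$functional_group == "control" & !stimuli$is_control))
    stop("stimuli with functional group 'control' must be flagged is_control")
  stimuli <- as.data.frame(stimuli, stringsAsFactors = FALSE)
  attr(stimuli, "panel_name") <- panel_name
  class(stimuli) <- c("odor_panel", "data.frame")
  stimuli
}

#' @rdname odor_panel
#' @param include_control include the air control stimulus (default `TRUE`).
#' @export
aliphatic_panel <- function(include_control = TRUE) {
  chain <- rep(6:9, times = 4)
  name <- c("1-hexanol", "1-heptanol", "1-octanol", "1-nonanol",
            "2-hexanol", "2-heptanol", "2-octanol", "2-nonanol",
            "hexanal", "heptanal", "octanal", "nonanal",
            "2-hexanone", "2-heptanone", "2-octanone", "2-nonanone")
  group <- rep(c("primary_alcohol", "secondary_alcohol", "aldehyde", "ketone"),
               each = 4)
  # mmHg at 25 C, literature values (see package vignette)
  vp <- c(0.928, 0.217, 0.0794, 0.0229,
          3.97,  1.07,  0.377,  0.113,
          11.3,  3.52,  1.18,   0.37,
          11.6,  3.86,  1.35,   0.46)
  tab <- data.frame(name = name, functional_group = group,
                    chain_length = chain, vapor_pressure = vp,
                    is_control = FALSE, stringsAsFactors = FALSE)
  if (include_control)
    tab <- rbind(tab, data.frame(name = "air", functional_group = "control",
                                 chain_length = NA_integer_,
                                 vapor_pressure = NA_real_,
                                 is_control = TRUE))
  p <- odor_panel(tab, panel_name = "aliphatic16")
  n_aliph <- sum(!p$is_control)
  stopifnot(n_aliph == 16L)
  p
}

#' @export
print.odor_panel <- function(x, ...) {
  cat("Odor panel '", attr(x, "panel_name") %||% "?", "': ", nrow(x),
      " stimuli (", sum(x$is_control), " control)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# latent chemical coordinates used by the synthetic generator:
# carbon chain length, oxygen moiety (C=O vs C-OH) and subtype within moiety
odor_latent <- function(panel) {
  moiety <- ifelse(panel$functional_group %in% c("aldehyde", "ketone"), 1, -1)
  subtype <- ifelse(panel$functional_group %in% c("primary_alcohol", "aldehyde"),
                    -1, 1)
  data.frame(name = panel$name,
             chain = panel$chain_length,
             moiety = ifelse(panel$is_control, NA_real_, moiety),
             subtype = ifelse(panel$is_control, NA_real_, subtype),
             stringsAsFactors = FALSE)
}
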