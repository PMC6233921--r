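#' Built-in and custom environment schedules
#'
#' Construct the per-generation NaCl concentration a regime faces. Three
#' built-in regimes mirror the experimental design: \describe{
#'   \item{sudden}{305 mM from generation 1 onwards.}
#'   \item{gradual}{33 mM at generation 1, increasing by 8 mM per generation
#'     until reaching 305 mM at generation 35, then constant 305 mM.}
#'   \item{control}{constant 25 mM, the ancestral condition.}
#' }
#'
#' @param regime one of "sudden", "gradual", "control", or any label when
#'   `env` is supplied.
#' @param horizon number of generations the schedule must cover.
#' @param env optional explicit numeric vector of environment values
#'   (generation 1..horizon); overrides the built-ins.
#' @param high,low,start,step tunables of the built-ins: plateau concentration
#'   (305 mM), control concentration (25 mM), gradual start (33 mM) and
#'   per-generation increment (8 mM).
#' @return an [EnvSchedule-class].
#' @examples
#' s <- envSchedule("gradual", horizon = 50)
#' scheduleEnv(s, c(1, 35, 50))   # 33, 305, 305
#' @export
envSchedule <- function(regime, horizon = 100L, env = NULL,
                        high = 305, low = 25, start = 33, step = 8) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  if (is.null(env)) {
    env <- switch(regime,
      sudden  = rep(high, horizon),
      gradual = pmin(start + step * (seq_len(horizon) - 1L), high),
      control = rep(low, horizon),
      stop("unknown built-in regime '", regime,
           "'; supply env= for a custom schedule")
    )
  } else {
    if (length(env) < horizon)
      stop("custom env covers ", length(env), " generations, need ", horizon)
    env <- env[seq_len(horizon)]
  }
  new("EnvSchedule", regime = regime, env = as.numeric(env))
}

#' Environment value(s) at given generations
#'
#' @param schedule an [EnvSchedule-class].
#' @param generations integer vector of generations (1-based).
#' @return numeric vector of environment values.
#' @export
scheduleEnv <- function(schedule, generations) {
  stopifnot(is(schedule, "EnvSchedule"))
  generations <- as.integer(generations)
  bad <- generations < 1L | generations > length(schedule@env)
  if (any(bad))
    stop("schedule '", schedule@regime, "' does not cover generation(s) ",
         paste(generations[bad], collapse = ", "))
  schedule@env[generations]
}

#' Number of generations a schedule covers
#' @param schedule an [EnvSchedule-class].
#' @export
scheduleHorizon <- function(schedule) length(schedule@env)

#' Read schedules from a tab-separated table
#'
#' Expects columns `regime`, `generation`, `env_mM`. Rows may be sparse: the
#' environment is filled forward piecewise-constant from the last stated
#' generation. Every regime must state a value for generation 1.
#'
#' @param path file path.
#' @param horizon number of generations each schedule must cover.
#' @return named list of [EnvSchedule-class] objects, one per regime.
#' @export
readScheduleTable <- function(path, horizon = 100L) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  requireCols(df, c("regime", "generation", "env_mM"), "schedule table")
  out <- lapply(split(df, df$regime), function(d) {
    d <- d[order(d$generation), , drop = FALSE]
    if (d$generation[1] != 1L)
      stop("regime '", d$regime[1], "' must state generation 1")
    env <- rep(NA_real_, horizon)
    for (i in seq_len(nrow(d))) {
      g <- d$generation[i]
      if (g <= horizon) env[g:horizon] <- d$env_mM[i]
    }
    envSchedule(d$regime[1], horizon = horizon, env = env)
  })
  out
}

#' Write schedules to a tab-separated table
#'
#' Dense form (one row per generation), the inverse of [readScheduleTable()].
#'
#' @param schedules named list of [EnvSchedule-class] objects.
#' @param path output file path.
#' @export
writeScheduleTable <- function(schedules, path) {
  rows <- do.call(rbind, lapply(schedules, function(s)
    data.frame(regime = s@regime, generation = seq_along(s@env),
               env_mM = s@env)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "EnvSchedule", function(object) {
  cat("EnvSchedule '", object@regime, "': ", length(object@env),
      " generations, ", object@env[1], " -> ",
      object@env[length(object@env)], " mM\n", sep = "")
})
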