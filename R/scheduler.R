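# Minute-granular linac scheduling: a day is tiled by large blocks
# ("Slot L", default 1 h), each subdivided into 1-minute unit slots
# ("Slot S"). Appointments occupy contiguous unit-slot runs of exactly
# their predicted length (ceiled to whole minutes); traffic-light state
# indicators summarize the remaining capacity of each block. A fixed-block
# booking baseline is provided for comparison.

.parse_clock <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("bad clock time '", x, "'", call. = FALSE)
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

.fmt_clock <- function(minutes) {
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

.empty_appointments <- function() {
  data.frame(patient_id = character(0), required_units = integer(0),
             start_minute = integer(0), assigned = logical(0),
             stringsAsFactors = FALSE)
}

.empty_tasks <- function() {
  data.frame(task_id = character(0), category = character(0),
             duration_min = integer(0), start_minute = integer(0),
             assigned = logical(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Build an empty schedule day
#'
#' Tiles the operating window `[open, close)` with large blocks of
#' `slot_l_length` minutes, each made of 1-minute unit slots. A window not
#' divisible by the block length gets a final shorter block (logged).
#'
#' @param open,close Clock times (`"HH:MM"`) or minutes since midnight.
#' @param slot_l_length Block length in minutes (default 60).
#' @param weekend Whether this day is a weekend day (governs which
#'   non-treatment task categories may be placed).
#' @return An object of class `schedule_day` with all unit slots free.
#' @export
build_day <- function(open = "08:00", close = "18:00", slot_l_length = 60L,
                      weekend = FALSE) {
  open_min <- .parse_clock(open)
  close_min <- .parse_clock(close)
  if (close_min <= open_min) stop("close time must be after open time",
                                  call. = FALSE)
  if (slot_l_length < 1) stop("slot_l_length must be >= 1", call. = FALSE)
  total <- close_min - open_min
  starts <- seq.int(0L, total - 1L, by = slot_l_length)
  lengths <- pmin(slot_l_length, total - starts)
  log <- character(0)
  if (total %% slot_l_length != 0) {
    log <- sprintf("window of %d min not divisible by %d; final block is %d min",
                   total, slot_l_length, lengths[length(lengths)])
  }
  structure(list(
    open_min = open_min, close_min = close_min,
    slot_l_length = as.integer(slot_l_length), weekend = weekend,
    blocks = data.frame(index = seq_along(starts), start = starts,
                        length = lengths),
    occupant = rep(NA_character_, total),
    occ_kind = rep(NA_character_, total),
    appointments = .empty_appointments(),
    tasks = .empty_tasks(),
    log = log
  ), class = "schedule_day")
}

#' Total, occupied and free minutes of a day
#' @param day A `schedule_day`.
#' @return Integer minute counts.
#' @export
total_minutes <- function(day) length(day$occupant)

#' @rdname total_minutes
#' @export
occupied_minutes <- function(day) sum(!is.na(day$occupant))

#' @rdname total_minutes
#' @export
free_minutes <- function(day) sum(is.na(day$occupant))

# Free contiguous runs, per block (or across the whole day when spanning is
# allowed). Returns data.frame(start, length), day-relative 0-based starts.
.free_runs <- function(day, within_blocks = TRUE) {
  runs_of <- function(free, offset) {
    r <- rle(free)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(start = offset + starts[r$values],
               length = r$lengths[r$values])
  }
  if (!within_blocks) {
    return(runs_of(is.na(day$occupant), 0L))
  }
  out <- lapply(seq_len(nrow(day$blocks)), function(i) {
    b <- day$blocks[i, ]
    idx <- seq.int(b$start + 1L, b$start + b$length)
    runs_of(is.na(day$occupant[idx]), b$start)
  })
  do.call(rbind, out)
}

.occupy <- function(day, start, length, id, kind) {
  idx <- seq.int(start + 1L, start + length)
  stopifnot(all(is.na(day$occupant[idx])))
  day$occupant[idx] <- id
  day$occ_kind[idx] <- kind
  day
}

#' Reserve the daily machine QA at the start of the day
#'
#' Daily output and mechanical checks precede the first treatment; the
#' reservation occupies the first unit slots of the first block. Duration
#' must be 0 (no reservation) or within 10--20 min, the operational range
#' for a daily check.
#'
#' @param day A `schedule_day`.
#' @param minutes QA duration in minutes (default 20).
#' @return The day with the QA task placed.
#' @export
reserve_daily_qa <- function(day, minutes = 20L) {
  minutes <- as.integer(minutes)
  if (minutes == 0L) return(day)
  if (minutes < 10L || minutes > 20L) {
    stop("daily QA duration must be within [10, 20] minutes, got ", minutes,
         call. = FALSE)
  }
  first_len <- day$blocks$length[1]
  if (minutes > first_len || any(!is.na(day$occupant[seq_len(minutes)]))) {
    stop("insufficient room for a ", minutes,
         "-min daily QA at the start of the day", call. = FALSE)
  }
  day <- .occupy(day, 0L, minutes, "daily_qa", "task")
  day$tasks <- rbind(day$tasks, data.frame(
    task_id = "daily_qa", category = "daily_qa", duration_min = minutes,
    start_minute = 0L, assigned = TRUE, reason = "", stringsAsFactors = FALSE))
  day
}

#' Schedule one appointment into the day
#'
#' The predicted duration is ceiled to whole minutes (unit slots admit no
#' partial occupation) and placed in the earliest contiguous free run that
#' can hold it (`first_fit`), or in the tightest adequate run (`best_fit`).
#' By default an appointment may not span a block boundary. If no adequate
#' run exists the appointment is recorded as unassigned — a reported
#' outcome, not an error.
#'
#' @param day A `schedule_day`.
#' @param patient_id Appointment identifier.
#' @param duration_s Predicted total duration in seconds (> 0).
#' @param policy `"first_fit"` or `"best_fit"`.
#' @param allow_spanning Permit runs crossing block boundaries.
#' @return The day with the appointment placed or recorded unassigned.
#' @export
schedule_appointment <- function(day, patient_id, duration_s,
                                 policy = c("first_fit", "best_fit"),
                                 allow_spanning = FALSE) {
  policy <- match.arg(policy)
  units <- as.integer(ceiling(duration_s / 60))
  if (units < 1) stop("appointment requires at least one unit slot",
                      call. = FALSE)
  runs <- .free_runs(day, within_blocks = !allow_spanning)
  fits <- runs[runs$length >= units, , drop = FALSE]
  row <- data.frame(patient_id = patient_id, required_units = units,
                    start_minute = NA_integer_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(fits) > 0) {
    pick <- if (policy == "first_fit") {
      which.min(fits$start)
    } else {
      order(fits$length, fits$start)[1]
    }
    start <- fits$start[pick]
    day <- .occupy(day, start, units, patient_id, "appointment")
    row$start_minute <- start
    row$assigned <- TRUE
  }
  day$appointments <- rbind(day$appointments, row)
  day
}

#' Schedule a batch of appointments in order
#'
#' @param day A `schedule_day`.
#' @param appointments Data frame with columns `patient_id` and `duration_s`.
#' @inheritParams schedule_appointment
#' @return The day after attempting every appointment in row order.
#' @export
schedule_cohort <- function(day, appointments, policy = "first_fit",
                            allow_spanning = FALSE) {
  for (i in seq_len(nrow(appointments))) {
    day <- schedule_appointment(day, appointments$patient_id[i],
                                appointments$duration_s[i],
                                policy = policy,
                                allow_spanning = allow_spanning)
  }
  day
}

.state_color <- function(free, thresholds) {
  if (free < thresholds[3]) "red"
  else if (free < thresholds[2]) "orange"
  else if (free > thresholds[1]) "green"
  else "orange"
}

#' Capacity state indicator of one block
#'
#' Traffic-light summary of the remaining free minutes in a block: `"red"`
#' below the lowest threshold (default < 5 min), `"orange"` below the middle
#' threshold (< 10 min), `"green"` above the top threshold (> 20 min). Free
#' time between the middle and top thresholds (10--20 min inclusive) maps to
#' `"orange"`: enough room for short tasks but not for a full appointment, so
#' the conservative flag applies. The rule is total over `0..slot_l_length`.
#'
#' @param day A `schedule_day`.
#' @param index Block index (1-based).
#' @param thresholds Strictly decreasing triple `(green_above, orange_below,
#'   red_below)` in minutes; default `c(20, 10, 5)`.
#' @return List with `color` and `free_minutes`.
#' @export
slot_state <- function(day, index, thresholds = c(20, 10, 5)) {
  if (!(index %in% day$blocks$index)) stop("no block with index ", index,
                                           call. = FALSE)
  if (!(thresholds[1] > thresholds[2] && thresholds[2] > thresholds[3])) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  b <- day$blocks[day$blocks$index == index, ]
  idx <- seq.int(b$start + 1L, b$start + b$length)
  free <- sum(is.na(day$occupant[idx]))
  list(color = .state_color(free, thresholds), free_minutes = free)
}

#' Capacity states of every block in a day
#'
#' @inheritParams slot_state
#' @return Data frame with columns `index`, `start` (clock), `free_minutes`,
#'   `color`.
#' @export
day_states <- function(day, thresholds = c(20, 10, 5)) {
  st <- lapply(day$blocks$index, slot_state, day = day,
               thresholds = thresholds)
  data.frame(index = day$blocks$index,
             start = .fmt_clock(day$open_min + day$blocks$start),
             free_minutes = vapply(st, `[[`, numeric(1), "free_minutes"),
             color = vapply(st, `[[`, character(1), "color"),
             stringsAsFactors = FALSE)
}

#' Locate a block able to absorb an emergency case
#'
#' Returns the index of the green block with the largest contiguous free
#' run (no displacement of already-scheduled patients), or `NA` when no
#' block is green.
#'
#' @inheritParams slot_state
#' @return Block index or `NA`.
#' @export
find_emergency_slot <- function(day, thresholds = c(20, 10, 5)) {
  states <- day_states(day, thresholds)
  runs <- .free_runs(day, within_blocks = TRUE)
  best <- NA_integer_
  best_run <- -1L
  for (i in states$index[states$color == "green"]) {
    b <- day$blocks[day$blocks$index == i, ]
    in_block <- runs$start >= b$start & runs$start < b$start + b$length
    if (any(in_block)) {
      m <- max(runs$length[in_block])
      if (m > best_run) { best_run <- m; best <- i }
    }
  }
  best
}

#' Non-treatment task catalog
#'
#' Machine QA, patient-specific dosimetry verification and maintenance
#' activities that consume linac time, with their admissible durations and
#' placement rules: daily QA precedes treatment on workdays; weekly and
#' longer-period QA and both maintenance categories belong to weekends;
#' dosimetry verification and breakdown repair are flexible. Breakdown
#' repair has no defined duration range.
#'
#' @return Data frame with columns `category`, `min_minutes`, `max_minutes`,
#'   `placement`.
#' @export
task_catalog <- function() {
  data.frame(
    category = c("daily_qa", "weekly_monthly_annual_qa",
                 "dosimetry_verification", "breakdown_repair",
                 "routine_maintenance", "periodic_maintenance"),
    min_minutes = c(10, 120, 5, NA, 60, 120),
    max_minutes = c(20, 240, 8, NA, 90, 120),
    placement = c("workday_pre_treatment", "weekend", "flexible", "flexible",
                  "weekend", "weekend"),
    stringsAsFactors = FALSE
  )
}

#' Place a non-treatment task into the day
#'
#' Validates the duration against the task catalog, rejects weekend-only
#' categories from workday schedules (a reported outcome, not an error) and
#' otherwise places the task in the earliest block holding a free contiguous
#' run of the required length. `daily_qa` is routed to
#' [reserve_daily_qa()] since it must precede treatment.
#'
#' @param day A `schedule_day`.
#' @param category A [task_catalog()] category.
#' @param duration_min Task duration in minutes.
#' @param task_id Identifier (defaults to the category).
#' @return The day with the task placed or recorded as rejected.
#' @export
assign_nontreatment_task <- function(day, category, duration_min,
                                     task_id = category) {
  cat_tab <- task_catalog()
  if (!category %in% cat_tab$category) {
    stop("unknown task category '", category, "'", call. = FALSE)
  }
  spec <- cat_tab[cat_tab$category == category, ]
  duration_min <- as.integer(duration_min)
  if (!is.na(spec$min_minutes) &&
      (duration_min < spec$min_minutes || duration_min > spec$max_minutes)) {
    stop("validation error: ", category, " duration must be within [",
         spec$min_minutes, ", ", spec$max_minutes, "] minutes, got ",
         duration_min, call. = FALSE)
  }
  if (duration_min < 1) {
    stop("validation error: task duration must be >= 1 minute", call. = FALSE)
  }
  if (category == "daily_qa") return(reserve_daily_qa(day, duration_min))
  row <- data.frame(task_id = task_id, category = category,
                    duration_min = duration_min, start_minute = NA_integer_,
                    assigned = FALSE, reason = "", stringsAsFactors = FALSE)
  if (spec$placement == "weekend" && !day$weekend) {
    row$reason <- "weekend_only"
    day$tasks <- rbind(day$tasks, row)
    return(day)
  }
  # tasks longer than one block (e.g. maintenance) may span block boundaries
  runs <- .free_runs(day, within_blocks = duration_min <= day$slot_l_length)
  fits <- runs[runs$length >= duration_min, , drop = FALSE]
  if (nrow(fits) > 0) {
    start <- fits$start[which.min(fits$start)]
    day <- .occupy(day, start, duration_min, task_id, "task")
    row$start_minute <- start
    row$assigned <- TRUE
  } else {
    row$reason <- "no_capacity"
  }
  day$tasks <- rbind(day$tasks, row)
  day
}

#' Fixed-block booking baseline
#'
#' The conventional booking scheme: the day is divided into sections, each
#' section into a fixed number of equal slots, and every appointment
#' consumes one whole fixed slot regardless of its predicted duration. The
#' slot count caps capacity; surplus appointments stay unassigned. Fixed
#' slots overlapping already-occupied minutes (e.g. a QA reservation) are
#' unavailable.
#'
#' @param day A `schedule_day` (its occupancy is the starting point).
#' @param appointments Data frame with columns `patient_id`, `duration_s`.
#' @param section_length Section length in minutes (default 60); must be
#'   divisible by `slots_per_section`.
#' @param slots_per_section Fixed slots per section (default 4).
#' @return A `block_schedule_day` (also a `schedule_day`) with fields
#'   `fixed_slot_length` and `n_fixed_slots`.
#' @export
block_baseline_schedule <- function(day, appointments, section_length = 60L,
                                    slots_per_section = 4L) {
  if (section_length %% slots_per_section != 0) {
    stop("section_length (", section_length, ") not divisible by ",
         slots_per_section, " slots", call. = FALSE)
  }
  slot_len <- section_length %/% slots_per_section
  total <- total_minutes(day)
  n_sections <- total %/% section_length
  if (total %% section_length != 0) {
    day$log <- c(day$log, sprintf(
      "block baseline: %d min remainder beyond %d whole sections unused",
      total %% section_length, n_sections))
  }
  slot_starts <- seq.int(0L, n_sections * section_length - 1L, by = slot_len)
  available <- vapply(slot_starts, function(s) {
    all(is.na(day$occupant[seq.int(s + 1L, s + slot_len)]))
  }, logical(1))
  free_slots <- slot_starts[available]
  apps <- .empty_appointments()
  for (i in seq_len(nrow(appointments))) {
    units <- as.integer(ceiling(appointments$duration_s[i] / 60))
    row <- data.frame(patient_id = appointments$patient_id[i],
                      required_units = units, start_minute = NA_integer_,
                      assigned = FALSE, stringsAsFactors = FALSE)
    if (length(free_slots) > 0) {
      start <- free_slots[1]
      free_slots <- free_slots[-1]
      day <- .occupy(day, start, slot_len, appointments$patient_id[i],
                     "appointment")
      row$start_minute <- start
      row$assigned <- TRUE
    }
    apps <- rbind(apps, row)
  }
  day$appointments <- rbind(day$appointments, apps)
  day$fixed_slot_length <- slot_len
  day$n_fixed_slots <- sum(available)
  class(day) <- c("block_schedule_day", class(day))
  day
}

#' Utilization report for a schedule day, or a minute-vs-block comparison
#'
#' For one day: occupied, free and total minutes, patients assigned and
#' unassigned, tasks, per-block capacity states, and (for a fixed-block
#' schedule) the idle minutes locked inside fixed slots by appointments
#' shorter than the slot. For a pair of days the report adds the difference
#' in free minutes and in patients assigned (first minus second).
#'
#' @param day A `schedule_day`.
#' @param baseline Optional second `schedule_day` to compare against
#'   (typically the fixed-block baseline).
#' @param thresholds State indicator thresholds, see [slot_state()].
#' @return A list of class `utilization_report`.
#' @export
utilization_report <- function(day, baseline = NULL,
                               thresholds = c(20, 10, 5)) {
  one <- function(d) {
    rep_ <- list(
      total_minutes = total_minutes(d),
      occupied_minutes = occupied_minutes(d),
      free_minutes = free_minutes(d),
      patients_assigned = sum(d$appointments$assigned),
      patients_unassigned = sum(!d$appointments$assigned),
      tasks_assigned = sum(d$tasks$assigned),
      slot_states = day_states(d, thresholds)
    )
    if (inherits(d, "block_schedule_day")) {
      a <- d$appointments[d$appointments$assigned, , drop = FALSE]
      rep_$fixed_slot_length <- d$fixed_slot_length
      rep_$internal_idle_minutes <-
        sum(pmax(0, d$fixed_slot_length - a$required_units))
    }
    rep_
  }
  out <- one(day)
  if (!is.null(baseline)) {
    out <- list(
      minute_schedule = out,
      baseline = one(baseline),
      free_minutes_difference = free_minutes(day) - free_minutes(baseline),
      patients_assigned_difference =
        sum(day$appointments$assigned) - sum(baseline$appointments$assigned)
    )
  }
  class(out) <- "utilization_report"
  out
}

# Occupied contiguous runs with occupant id and kind.
.occupied_runs <- function(day) {
  occ <- ifelse(is.na(day$occupant), "", paste0(day$occ_kind, "\r", day$occupant))
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != ""
  if (!any(keep)) {
    return(data.frame(kind = character(0), id = character(0),
                      start_minute = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(r$values[keep], "\r", fixed = TRUE)
  data.frame(kind = vapply(parts, `[[`, character(1), 1),
             id = vapply(parts, `[[`, character(1), 2),
             start_minute = starts[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Write a schedule as JSON or as a flat CSV
#'
#' The JSON form carries day metadata and one entry per block: index, start
#' clock time, capacity state, free minutes and the occupant runs (kind, id,
#' day-relative start minute, length). The CSV form is flat: one row per
#' occupied unit-slot run.
#'
#' @param day A `schedule_day`.
#' @param path Output path.
#' @param thresholds State thresholds, see [slot_state()].
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(day, path, thresholds = c(20, 10, 5)) {
  runs <- .occupied_runs(day)
  states <- day_states(day, thresholds)
  blocks <- lapply(seq_len(nrow(day$blocks)), function(i) {
    b <- day$blocks[i, ]
    in_b <- runs$start_minute >= b$start & runs$start_minute < b$start + b$length
    list(index = b$index,
         start = .fmt_clock(day$open_min + b$start),
         state = states$color[i],
         free_minutes = states$free_minutes[i],
         occupants = lapply(which(in_b), function(j) {
           list(kind = runs$kind[j], id = runs$id[j],
                start_minute = runs$start_minute[j], length = runs$length[j])
         }))
  })
  payload <- list(
    open = .fmt_clock(day$open_min), close = .fmt_clock(day$close_min),
    slot_l_length = day$slot_l_length, weekend = day$weekend,
    total_minutes = total_minutes(day), free_minutes = free_minutes(day),
    unassigned_appointments =
      day$appointments$patient_id[!day$appointments$assigned],
    slots = blocks
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
write_schedule_csv <- function(day, path) {
  runs <- .occupied_runs(day)
  runs$start_clock <- .fmt_clock(day$open_min + runs$start_minute)
  utils::write.csv(runs, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.schedule_day <- function(x, ...) {
  cat(sprintf("<schedule_day> %s-%s, %d blocks of %d min, %d/%d min free\n",
              .fmt_clock(x$open_min), .fmt_clock(x$close_min),
              nrow(x$blocks), x$slot_l_length, free_minutes(x),
              total_minutes(x)))
  cat(sprintf("  appointments: %d assigned, %d unassigned; tasks: %d\n",
              sum(x$appointments$assigned), sum(!x$appointments$assigned),
              nrow(x$tasks)))
  invisible(x)
}
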