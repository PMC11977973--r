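#' Pending-completion event queue
#'
#' The queue holds delayed completions that have been scheduled but not yet
#' executed: for each event, its completion time and the per-species change
#' to apply then. This is the memory that makes a delayed simulation
#' non-Markovian. Events pop in nondecreasing completion time, with ties
#' broken first-in-first-out.
#'
#' The queue additionally tracks, per species, the total *committed pending
#' decrement* (the molecules that scheduled events will remove). A state
#' update is feasible only if it leaves every species with at least its
#' committed decrement; this guarantees that executing a completion can never
#' drive a count negative, so every conflict is caught (and resolved, see
#' [resolve_conflict()]) at the moment a reaction fires or schedules.
#'
#' Internally the queue is a time-sorted array with lazy (tombstone)
#' deletion, held in a closure environment so that scheduling with constant
#' delays, popping, and cancelling a conflicting event are all O(1)
#' amortised. Queues are mutable; the scheduling and popping functions
#' modify their argument and return it invisibly.
#'
#' @param n_species number of species in the network.
#' @return an object of class `pending_event_queue`.
#' @examples
#' q <- event_queue(1)
#' schedule_completion(q, 5, delta = -1)
#' schedule_completion(q, 3, delta = -1)
#' queue_peek(q)   # 3
#' @export
event_queue <- function(n_species) {
  ns <- as.integer(n_species)
  cap <- 64L
  times <- numeric(cap)
  rxn <- integer(cap)
  delta <- matrix(0, ns, cap)
  dead <- logical(cap)
  head <- 1L           # first (possibly tombstoned) slot
  tail <- 0L           # last used slot
  n_alive <- 0L
  committed <- numeric(ns)

  settle <- function() {
    h <- head
    while (h <= tail && dead[h]) h <- h + 1L
    head <<- h
  }

  grow <- function() {
    # compact away the dead prefix and interior tombstones, keep >= 25% free
    alive <- if (head <= tail) which(!dead[head:tail]) + head - 1L else integer(0)
    n <- length(alive)
    newcap <- cap
    while (newcap < n + 64L || (newcap - n) < newcap %/% 4L) newcap <- newcap * 2L
    nt <- numeric(newcap); nr <- integer(newcap)
    nd <- matrix(0, ns, newcap); ndead <- logical(newcap)
    if (n > 0L) {
      nt[seq_len(n)] <- times[alive]
      nr[seq_len(n)] <- rxn[alive]
      nd[, seq_len(n)] <- delta[, alive, drop = FALSE]
    }
    times <<- nt; rxn <<- nr; delta <<- nd; dead <<- ndead
    cap <<- newcap; head <<- 1L; tail <<- n
  }

  push <- function(time, dlt, reaction) {
    if (tail + 1L > cap) grow()
    # insertion point from the tail: constant delays always append
    i <- tail
    while (i >= head && times[i] > time) i <- i - 1L
    if (i < tail) {
      shift <- (i + 1L):tail
      times[shift + 1L] <<- times[shift]
      rxn[shift + 1L] <<- rxn[shift]
      delta[, shift + 1L] <<- delta[, shift, drop = FALSE]
      dead[shift + 1L] <<- dead[shift]
    }
    times[i + 1L] <<- time
    rxn[i + 1L] <<- reaction
    delta[, i + 1L] <<- dlt
    dead[i + 1L] <<- FALSE
    tail <<- tail + 1L
    n_alive <<- n_alive + 1L
    committed <<- committed - dlt * (dlt < 0)
    invisible(NULL)
  }

  peek <- function() {
    if (n_alive == 0L) return(Inf)
    if (dead[head]) settle()
    times[head]
  }

  pop <- function() {
    if (n_alive == 0L) return(NULL)
    if (dead[head]) settle()
    h <- head
    ev <- list(time = times[h], delta = delta[, h], reaction = rxn[h])
    head <<- h + 1L
    n_alive <<- n_alive - 1L
    committed <<- committed + ev$delta * (ev$delta < 0)
    ev
  }

  drop_slot <- function(pos) {
    d <- delta[, pos]
    committed <<- committed + d * (d < 0)
    dead[pos] <<- TRUE
    delta[, pos] <<- 0          # keeps candidate scans truthful
    n_alive <<- n_alive - 1L
    if (pos == head) settle()
    invisible(NULL)
  }

  # uniform draw among alive events decrementing species s; -1 when none.
  # Rejection sampling is O(1) in the conflict-heavy regime (where most
  # queued events decrement s); falls back to one full scan.
  pick_decrementer <- function(s) {
    if (n_alive == 0L) return(-1L)
    span <- tail - head + 1L
    for (k in 1:16) {
      slot <- head + sample.int(span, 1L) - 1L
      if (delta[s, slot] < 0) return(slot)
    }
    idx <- head:tail
    cand <- idx[delta[s, idx] < 0]
    if (!length(cand)) return(-1L)
    cand[sample.int(length(cand), 1L)]
  }

  q <- environment()
  class(q) <- "pending_event_queue"
  q
}

#' @export
print.pending_event_queue <- function(x, ...) {
  n <- queue_size(x)
  cat(sprintf("<pending event queue: %d event%s", n, if (n == 1) "" else "s"))
  if (n > 0) cat(sprintf(", next completion at t = %g", queue_peek(x)))
  cat(">\n")
  invisible(x)
}

#' Number of pending events
#' @param queue a [event_queue()].
#' @return integer count of scheduled, unexecuted completions.
#' @export
queue_size <- function(queue) queue$n_alive

#' Completion time of the next pending event
#' @param queue a [event_queue()].
#' @return the earliest completion time, or `Inf` for an empty queue.
#' @export
queue_peek <- function(queue) queue$peek()

#' Schedule a delayed completion
#'
#' Inserts an event into the queue, preserving the nondecreasing-time pop
#' order (ties keep insertion order). A zero delay is legal -- the caller
#' applies such an event immediately -- but a completion time in the past is
#' not.
#'
#' @param queue a [event_queue()].
#' @param time completion time (model time units).
#' @param delta per-species change to apply at completion.
#' @param reaction optional index of the scheduling reaction.
#' @return the queue, invisibly (modified in place).
#' @export
schedule_completion <- function(queue, time, delta, reaction = NA_integer_) {
  if (!is.finite(time)) stop("completion time must be finite")
  if (length(delta) != queue$ns)
    stop("event delta length does not match the species count")
  queue$push(time, delta, as.integer(reaction))
  invisible(queue)
}

#' Pop the earliest pending event
#' @param queue a [event_queue()].
#' @return list with `time`, `delta` and `reaction` of the popped event, or
#'   `NULL` when the queue is empty.
#' @export
pop_completion <- function(queue) queue$pop()

#' Resolve a conflict between a state update and pending delayed events
#'
#' A proposed update conflicts with the queue when it would leave some
#' species with fewer molecules than its committed pending decrements (in
#' the limiting case, with a negative count). Following the rule of randomly
#' removing one of the conflicting delayed events, this repeatedly removes
#' one uniformly chosen pending event that decrements a deficit species --
#' removed events never execute -- until the proposal is feasible.
#'
#' @param queue a [event_queue()].
#' @param counts the per-species counts *after* applying the proposal.
#' @param deficit_species optional integer indices of species in deficit;
#'   computed from `counts` and the queue's committed decrements if omitted.
#' @return the queue, invisibly (modified in place).
#' @export
resolve_conflict <- function(queue, counts, deficit_species = NULL) {
  repeat {
    deficit <- if (is.null(deficit_species))
      which(counts < queue$committed) else deficit_species
    deficit_species <- NULL  # recompute on later passes
    if (!length(deficit)) return(invisible(queue))
    pick <- -1L
    for (s in deficit) {
      pick <- queue$pick_decrementer(s)
      if (pick > 0L) break
    }
    if (pick < 0L)
      stop("unresolvable conflict: no pending event decrements the deficit species")
    queue$drop_slot(pick)
  }
}
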