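---
title: "Simulating SBML models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SBML models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlsim)
```

`sbmlsim` integrates SBML (Level 2 Version 4 and Level 3 Version 1)
models as systems of ordinary differential equations, extended with the
discontinuous and implicit constructs the standard allows: events with
priorities, persistence and delays; algebraic rules (turning the ODE
into a DAE); `fast` reactions at quasi-equilibrium; and delay
expressions that make the system a delay differential equation. This
vignette explains the model of computation, the numerical choices, and
the places where the design was genuinely open.

## From SBML to equations

A loaded model is compiled once, up front. Every MathML expression is
parsed to an abstract syntax tree; `FunctionDefinition` calls are
expanded in place (structural substitution of actual arguments for the
formal parameters, which is capture-free because a definition body may
only reference its own formals and global identifiers), and `piecewise`
expressions are rewritten into arithmetic: each branch value is
multiplied by its condition guarded with the negations of all earlier
conditions, and the guarded terms are summed. Two consequences of this
rewriting are worth knowing:

* overlapping conditions resolve *first-true-wins* — later branches are
  explicitly blocked by `NOT` guards of earlier ones;
* a piecewise with no true condition and no `otherwise` evaluates to 0.
  The standard leaves this undefined; the loader logs a note when such
  an expression is compiled.

The transformed trees are then linearized post-order into reverse
Polish programs evaluated on an explicit stack, so expression
evaluation never recurses. Every compiled program is checked statically
for stack balance (net effect +1, no underflow anywhere). Relational
and logical opcodes return 1.0/0.0 and any nonzero operand counts as
true; division by zero and out-of-domain arguments propagate IEEE
infinities and NaN rather than raising errors.

Species are stored internally as **amounts** throughout; concentrations
are materialized on demand as amount divided by the current compartment
size. This keeps the dynamics correct if a compartment's size changes
during the run. Kinetic laws are read as extensive rates
(amount/time), per the SBML specification, so the amount derivative of
a species is the stoichiometry-weighted sum of kinetic-law values. A
rate rule on a concentration-based species is scaled by the compartment
size before it is applied to the stored amount.

Each `AlgebraicRule` contributes one constraint `g(x) = 0` and claims
one solved-for ("algebraic") variable: the unique variable referenced
by the rule that is not otherwise determined (not constant, not
differential through reactions or rate rules, not an assignment-rule
target). If more than one candidate remains, the leftmost in state
order is used and a note is logged; full bipartite matching would be
needed only for models that the public test corpus does not exercise.
The constraints are Newton-solved after every accepted step (and at
t = 0), so the DAE is handled in a post-stabilization style rather than
by a fully implicit DAE integrator — adequate at the step sizes used
for these models, and reported honestly by the constraint residual
staying below the Newton tolerance (1e-10 by default).

## Nonlinear solves

All implicit machinery routes through one k-dimensional Newton
iteration built on a hand-written dense LU decomposition with partial
pivoting (forward elimination, backward substitution). Jacobians are
forward finite differences with step `sqrt(machine epsilon) *
max(|x_j|, 1)` per component — half the cost of central differences,
with accuracy that the default residual tolerance (1e-10, max 100
iterations) comfortably absorbs. Newton is undamped, as in a
straightforward reference implementation; when it fails inside an
implicit integrator step the step is halved (up to 10 times) before the
run aborts. A pivot below 1e-14 reports a singular matrix. One
practical consequence of plain Newton worth knowing: symmetric starting
points can sit exactly on a singular manifold of the Jacobian (for
instance `{x+y-3, xy-2}` started at `x = y`), and the solver will
report the singularity rather than escape it.

## Integrators

Eight steppers are provided, all written from scratch:

| family | type | order | notes |
|---|---|---|---|
| `euler` | explicit, fixed | 1 | |
| `rk4` | explicit, fixed | 4 | default method |
| `adams_bashforth` | explicit, multistep | 1–4 | |
| `backward_euler` | implicit, fixed | 1 | Newton per step |
| `adams_moulton` | implicit, multistep | 1–4 | order 1 = implicit Euler, 2 = trapezoid |
| `gear` | implicit, multistep (BDF) | 1–4 | fixed step |
| `rkf45` | embedded 4(5), adaptive | — | Fehlberg tableau |
| `cash_karp` | embedded 4(5), adaptive | — | Cash–Karp tableau |

Fixed-step methods take `refinement` internal steps per output interval
(default 10), so the decay example below at 50 output steps uses 500
internal steps. Adaptive methods free-run: the local error is
`max |y5 - y4| / (atol + rtol |y5|)`, a step is accepted iff that is at
most 1 (boundary inclusive), the next step is
`h * min(5, max(0.1, 0.9 error^(-1/5)))` (safety 0.9, growth cap 5,
shrink floor 0.1 — conventional controller constants), and the
fifth-order solution is the one advanced. Step underflow below
`duration * 1e-12` aborts with advice to use an implicit method.

Multistep methods ramp up **within their own family**: the first step
uses the order-1 member (BDF1, implicit Euler, or explicit Euler for
Adams–Bashforth), the second order 2, and so on until the requested
order is reached. The more common RK4 startup was rejected
deliberately: an explicit fourth-order startup step destroys the
A-stability that is the reason to choose Gear or Adams–Moulton in the
first place (on `y' = -1000y` at `h = 0.1` an RK4 step amplifies the
solution by ~3×10^6), while the low-order implicit members are stable
from the very first step. The history is invalidated — and the ramp-up
restarted — whenever an event assignment or fast-reaction
equilibration changes the state discontinuously, and whenever step
clamping breaks the uniform spacing the fixed-coefficient formulas
assume.

## Events

Triggers are boolean expressions watched for false→true edges at
accepted-step boundaries; there is no root-finding refinement of the
crossing time, so the internal step density bounds the timing error of
an event (this is the main accuracy consideration when simulating
event-heavy models — raise `refinement` if event timing matters).
Level 2 models treat all triggers as already true at t = 0, so nothing
fires from the initial condition; Level 3 honours the trigger's
`initialValue` and can fire at t = 0.

Simultaneously triggered events enter a queue and are executed one at a
time: all priorities are evaluated in the current state, the
maximum-priority event runs (all of its assignment right-hand sides are
evaluated before any target is written), non-persistent queued events
whose triggers have meanwhile gone false are withdrawn, newly
edge-triggered events join the queue, and the loop repeats until the
queue empties (a guard of 10,000 executions catches livelocks). Events
without a `Priority` element rank below any numeric priority, and
remaining ties are broken randomly — seedable through
`sim_config(seed = )`, so runs are bit-reproducible.

An event with a `Delay` element is never executed in-cascade: its fire
time is the trigger time plus the delay evaluated at trigger time, and
with `useValuesFromTriggerTime` the assignment values are evaluated
immediately and frozen. The integrator clamps internal steps onto
pending fire times, so delayed assignments land exactly. A
non-persistent event whose trigger lapses while its assignment is
pending is cancelled.

## Delay expressions and history

`delay(expr, lag)` inside any expression is served by a history buffer
that records the full state vector at every accepted step for the whole
run (memory is linear in step count; retention is deliberately
unbounded because SBML lags need not be constant). Lookups linearly
interpolate between the two bracketing samples; queries before t = 0
return the initial value, the standard convention for constant
prehistory. On the first interval of `y'(t) = -y(t-1)` with `y ≡ 1` for
`t ≤ 0` the method of steps gives exactly `y(t) = 1 - t`, which the
simulator reproduces to rounding error — a sharper-than-usual test
because the derivative is exactly -1 throughout.

## Fast reactions

Reactions flagged `fast` are treated as at quasi-equilibrium relative
to everything else. After every accepted step (and at t = 0) the
affected species are replaced by the root of the square system formed
by the independent fast reaction rates set to zero plus the conserved
totals of the fast stoichiometry's left null space fixed at their
current values. The fast species are all dynamic species touched by a
fast reaction — slow reactions may also touch them, in which case the
slow fluxes move the conserved totals between equilibrations and the
equilibration restores the ratio (for `A ⇌ B` with `v = 2A - B`, the
ratio A:B = 1:2). Because the re-equilibration happens after each step
rather than inside it, the scheme carries O(h) splitting error in the
totals; with the default refinement this is invisible at output
precision, and halving the internal step halves it. This
quasi-equilibrium-after-step reading was chosen over operator splitting
within the step for its simplicity and because it matches the behaviour
expected by the public SBML test corpus.

## The simulation loop

Per internal step: clamp the step onto the next output time and the
next pending event fire time; advance with the configured stepper;
re-apply the assignment-rule closure; equilibrate the fast subsystem;
solve the algebraic constraints; append to the history; detect trigger
edges and run cascades; fire due delayed assignments; check Constraint
elements (violations are logged, not fatal — the standard does not
prescribe runtime behaviour, and halting would make many valid models
unusable). Output times are computed by multiplication
(`i * duration / steps`), never by accumulating h, so the grid carries
no floating-point drift. Output rows report species as amounts or
concentrations according to how each was declared, overridable per
variable.

## The fixture generator and what passing means

The package generates its own SBML documents (`make_fixture()`):
fifteen feature tags covering decay/chain/stiff kinetics, function
definitions, piecewise, all three rule types, the event variants,
delay expressions, fast reactions and boundary species, each emitted in
both L2V4 and L3V1 dialects where the feature exists in both. Default
constants are chosen so every fixture has a closed form or a
hand-checkable trace (decay: `10 e^{-0.5 t}`; the priority cascade:
S1 := 0 then E2 withdrawn; delayed capture: 5 at trigger time vs 7 at
fire time). These fixtures are *clean* models: modest stiffness, no
unit conversions, no exotic MathML, sizes of a handful of variables.
Passing the suite therefore demonstrates the semantics of each
construct and their interactions — it does not demonstrate performance
on large models, nor robustness to the pathological expressions real
curated models sometimes contain.

`run_suite_case()` reads the public SBML test corpus's case layout
(model file, `-settings.txt`, `-results.csv`) and applies its pass
criterion `|computed - expected| <= atol + rtol |expected|` per point.
The corpus itself is an external download and is not redistributed
here; the package's own tests exercise the harness on locally
synthesized cases whose reference trajectories come from closed forms
or from deSolve, an independent solver.

## Problem sizes used in the checks

The test and acceptance computations run at deliberately desk-scale
sizes, stated here as the package's own choices: decay with 500
internal RK4 steps; convergence orders from error ratios at h = 1/20 vs
1/40; the stiff probe at h = 0.1 for 10 steps; 100 random linear
systems up to 20×20; 1000 random expression trees of depth ≤ 8; the DDE
at h = 1e-3 over one delay interval; conservation over duration 100 at
h = 0.1; the fast-vs-stiff comparison over duration 5 with the
brute-force oracle at rate ×10^6 integrated by Gear-2.

## Known limitations

* No root-finding of trigger crossing times (timing error bounded by
  the internal step).
* Gear/Adams methods are fixed-step and fixed-order (1–4); no
  variable-order BDF.
* The algebraic-variable assignment is greedy document-order, not a
  full bipartite matching.
* No PDE, SDE or discrete-stochastic semantics; no SBML packages
  (comp, fbc), no unit validation; Level 1 documents are rejected.
* Rate rules on concentration-based species assume the compartment
  size constant over a step when scaling to amounts.
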