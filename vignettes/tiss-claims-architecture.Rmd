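---
title: "A two-level archetype architecture for TISS claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level archetype architecture for TISS claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissehr)
```

## The model

TISS, the Brazilian standard for authorization and claim exchange between
health plans and providers, defines forms and messages but no information
model. `tissehr` implements it on the two-level (dual-model) architecture:
a small, stable **reference model** of record structures, and **archetypes**
— constraint definitions over those structures — expressing each domain
concept. Forms are **templates**: named combinations of archetypes with
exclusions, occurrence narrowings and local code bindings, flattened into a
single operational constraint tree for validation and form generation.

The reference-model kernel covers exactly what TISS instances need:
compositions, sections, the clinical entry family (observation, evaluation,
instruction, action), the administrative entry, the four item structures,
elements, and a closed set of data values (text, coded text, date, datetime,
count, quantity, money, identifier). Deliberately out of scope are event
histories, versioning, folders and audit — none of which the claim content
uses.

Two representations of a claim coexist:

* **plain RM**: the claim header is an `ADMIN_ENTRY` whose elements carry
  submission id/date, billing date, status, and so on;
* **extended RM**: `ADMIN_ENTRY` is specialized into `SUBMISSION` (fixed
  attributes `submission_id`, `submission_date`, `submitter`, `submittee`,
  `original_submission`), `CLAIM` (`billing_date`) with professional
  (`performer`) and institutional (`participants`) subtypes,
  `AUTHORIZATION` (`requester`, and on responses `authorization_id` plus a
  validity interval) and `ANNEX` (`complements`); the composition gains an
  `ISM_TRANSITION` holding the claim status.

`convert_base_to_extended()` / `convert_extended_to_base()` move values
between the two representations losslessly (see *Conversion mapping*).

## The claim lifecycle

The billing cycle is request → authorization → claim → denied/completed,
with resubmission after refusal. Only the status list, the cycle and the
resubmission rule are fixed by the standard's description; the full
transition relation is not. The package uses the minimal relation
consistent with those three facts:

```{r}
transition_relation()
```

COMPLETED is the unique terminal state and every state is reachable from
SUBMITTED. Because real payers differ, the relation is exportable and
overridable via a JSON config (`write_transition_config()` /
`read_transition_config()`); every lifecycle API accepts an alternative
relation. Histories are validated structurally (initial state SUBMITTED,
pairwise legality, non-decreasing timestamps) and validation returns
findings, never exceptions.

## The ADL dialect

The parser covers exactly the constructs the TISS archetype definitions
use: `matches` blocks, `occurrences matches {l..u}`, `cardinality matches
{l..u; ordered|unordered}`, `DV_*` leaf constraints with the any-pattern
`{*}`, `allow_archetype` slots with `|`-separated include identifiers, and
trailing `--` comments, which become term labels. An optional `archetype`
header and a simple `ontology` section (`atNNNN = "text" ; "description"`)
support fixture authoring. Full ADL 1.4 — specialization, assumed values,
bindings sections — is out of scope.

Numerical and syntactic defaults:

* unstated occurrences default to `{1..1}` (the convention for archetype
  roots), and the canonical printer omits occurrences exactly when they are
  `{1..1}`, which makes printing a parse fixed point;
* term descriptions default to the term text when only comments exist;
* node ids must be unique within an archetype, and `at0000` is reserved for
  archetype roots.

Two institutional-claim definition listings — one `ADMIN_ENTRY`-rooted,
one `INSTITUTIONAL_CLAIM`-rooted — ship under `inst/extdata/adl/` as
reference fixtures. As published, both end inside the slot block; the
bundled files append the four closing braces needed to balance the tree and
are otherwise token-identical to the print. The fixture builder reproduces
them token-for-token (comments and whitespace aside), which the acceptance
suite checks.

## Fixture reconstruction decisions

The archetype inventory is reconstructed from the published tables plus the
two listings, which required a handful of judgment calls:

* The institutional claim's table row lists *type of claim* twice; the
  listing has eleven distinct elements, so the fixture follows the listing
  (codes `at0002..at0012`, slot at `at0015`, submission id and original
  submission repeatable `{0..*}`).
* The extended institutional claim keeps its *status* element (`at0005`):
  the published extended listing retains it even though status also lives
  in the ISM transition, and the extended inventory table omits it. The
  fixture follows the listing; the redundancy is the source material's.
* **Absorbed header sets.** The extended-model inventories drop, per
  archetype, exactly the elements the extended RM absorbs
  (`rm_absorbed_labels()`): the four submission/billing header fields
  everywhere; additionally *status* (→ ISM transition) except where the
  listing retains it; for authorizations *validity*, *authorization date*
  and *authorization number* (→ `validity`, response `submission_date`,
  `authorization_id`); and for the professional claim *validity* and *type
  of claim* — the latter because the `PROFESSIONAL_CLAIM` class itself
  determines the claim type, whereas an institutional claim still needs it
  to distinguish hospital, laboratory and clinic.
* The cost-cluster slot in both institutional listings includes
  `openEHR-EHR-CLUSTER.costs.v1` while the inventory names the archetype
  `total_costs`. The repository treats `costs` as an alias of
  `total_costs` rather than silently merging them; include matching and
  slot filling are alias-aware.
* The composition archetype's slot formally "includes each of the
  archetypes above", but cluster archetypes cannot sit in
  `COMPOSITION.content`; the slot therefore includes the seven
  entry-rooted archetypes, and clusters enter through the admin
  archetypes' cluster slots.
* Element value types default to text, as in the listings (even dates are
  `DV_TEXT` there); the only deviations are *date of encounter*
  (`DV_DATE_TIME`, as printed), monetary fields (`DV_MONEY`) and
  day/quantity counts (`DV_COUNT`), all recorded in the emitted
  `manifest.json`. Dates-as-text keep listing fidelity; the preferred
  modelling would be `DV_DATE`.
* *Number of living births* is a nested cluster of five count elements,
  following its parenthetical breakdown in the inventory.

## Templates: the eleven forms

The standard enumerates eleven forms (individual claim, consultation
claim, admission request/authorization/claim, tests-and-procedures
request/authorization/claim, dental evaluation, dental claim, other
charges) without listing which archetypes each selects. The shipped
templates are reconstructions from the form semantics: claim forms carry
the matching admin archetype plus evaluation and/or performed services;
admission forms fill the admission cluster; claim forms fill the total
costs cluster; dental forms use the odontologic evaluation. They are
config files (`*.tpl.json` — JSON rather than YAML, since the package
avoids a YAML dependency) naming the root composition archetype, slot
fills by flattened path, exclusions, occurrence overrides and code
bindings.

Exclusion is implemented as an occurrences override to `{0..0}` rather
than node deletion, so provenance stays total over the flattened tree and
an excluded element appearing in an instance is reported at its own path.
Overrides may only narrow. Flattening replaces each filled slot with the
filler trees while retaining a narrowed slot node, so that a foreign
filler in an instance is still recognized as a slot-include violation
rather than an unknown node. Code bindings accept any terminology id and
treat codes as opaque strings; terminology content is out of scope.

## Validation

`validate_instance()` walks instance and constraint trees in parallel and
reports **all** violations as findings (rule, instance path, severity) in
canonical path order — adjudication needs complete, deterministic reports,
not first-failure exceptions. Node-id matching is exact; the fixture set
is flat, so no specialization semantics are needed. Attributes the
archetype does not constrain (links, parties) are permitted: the archetype
constrains, it does not enumerate. Subtype substitutability follows the RM
type registry, so an extended claim entry satisfies an `ADMIN_ENTRY`
constraint. The template layer adds one rule beyond the core set,
`CODE_BINDING_VIOLATION`, for coded values outside their binding.

## Conversion mapping

Base → extended moves, by label: submission id, submission date, original
submission and billing date into the corresponding attributes; status into
the composition's ISM transition (timestamped with the composition's
context start time); and, for authorizations, validity (`"start/end"`) and
authorization number into `validity` and `authorization_id`, with
`is_response` true iff an authorization number is present. The submitter
and payer come from the entry's participations (functions `"submitter"`
and `"payer"`); the professional claim's performer and the authorization's
requester come from the entry's provider; an institutional claim's
`"professional"` participations become its participant list. Everything
else stays verbatim, and the inverse restores elements at their archetype
at-codes and participations in the canonical order (submitter, payer,
professionals, rest) — the order the generator emits — so the base →
extended → base round trip is the identity and the multiset of populated
(label, value) pairs is conserved in both directions.

One published mapping note is deliberately not followed: mapping the
authorization's *authorization date* onto the response's
`submission_date` would collide with the *submission date* element that
the same archetype also carries, breaking losslessness; *authorization
date* therefore stays a residual element. Converted entries also keep
their source archetype id (their node ids are the source's), which makes
the inverse direction unambiguous.

## The synthetic-data generator

The generator instantiates a flattened template: mandatory and
header-critical elements always, other optional elements with probability
0.9 (`fill = "all"` forces everything), values drawn from fixed pools.
Its stated world: parties are always `PARTY_IDENTIFIED` with one opaque
Brazilian-style identifier each (patient/plan number, professional council
id, provider and payer registry ids); amounts are uniform on R$10–5000
with two decimals; dates fall in a 20-day window of October 2011 with
admission ≤ discharge and requested days ≤ authorized days; status opens
as "submitted"; repeatable diagnoses appear once or twice. One RNG stream
is derived per (seed, template, index), so adding templates never shifts
existing outputs, and the same configuration is byte-identical.

It does **not** emulate real TISS data: no real identifier formats, no
realistic cost or volume distributions, no terminology-coded diagnoses or
procedures (codes are opaque strings), no multi-patient case mix beyond
one patient per composition. A green validity-by-construction test
therefore establishes that generator and validator agree on the constraint
semantics — not that the validator would accept or reject real-world
claims, which is what the mutant suite probes: each mutant minimally
injects one named violation and must be detected with its declared rule at
its declared path. The slot-filler-gap rule is the one exception — it
needs a repository gap, not an instance defect — and is exercised directly
in the validator tests.

## The exchange simulation

Transport is an in-process contract with the four REST verbs over
`/organizationID/{resource_id}`; an HTTP binding would be a thin adapter,
and the tests need no network. Resource ids are assigned monotonically per
organization and extract/submission/authorization ids come from seedable
counters, so runs are reproducible byte-for-byte; a fixed-start,
fixed-step clock timestamps every transition. The payer validates each
composition against its template (invalid → returned for correction with
the report attached as an annex), then applies a user-supplied policy;
approved authorization requests get an authorization id and a validity
period, everything else an adjudication annex. Responses reference their
request via `original_submission` and a link, exactly one response per
request. With `resubmit = TRUE` a denied submission is reopened
(DENIED → SUBMITTED) and resent once.

## Serialization and numeric choices

Compositions and extracts serialize to canonical JSON and XML derived from
a single canonical tree, so same-format and cross-format round trips are
structurally exact. Monetary amounts are parsed leniently ("1,200.00"),
rounded half-to-even at two decimals, and compared after parsing;
timestamps are canonicalized to `YYYY-MM-DDTHH:MM:SS` at construction.
Structural equality is defined on the canonical tree, which makes it an
equivalence relation by construction. All seeds are kept below 2^31.

## Known limitations

Terminology binding (the TISS semantic-content standard), the official
TISS XML schemas, security/privacy requirements, and archetype
specialization are out of scope. The eleven template-archetype assignments
are reconstructions, as are all at-codes outside the two published
listings. Moving `other_participations` down the class hierarchy so that
administrative entries could drop it entirely — a refactor the extended
model invites — is discussed here but intentionally not implemented: the
extended entries remain full entries, which keeps the two representations
convertible.
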