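---
title: "Concept matching for food intolerance scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept matching for food intolerance scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodont)
```

## The model

`foodont` scores how objectionable a packaged food product is for a
particular consumer by matching two concept lists through a food ontology:
the semantically enhanced consumer intolerance list $C$ and the product
ingredient list $P$. The ontology supplies three kinds of structure:
synonym edges (equivalence: "Ascorbic Acid" ≡ "E300" ≡ "Vitamin C"),
subclass (is-a) edges, and `hasGroup` edges, which are traversed like
subclass edges with the group as parent.

Each pair $(C_i, P_j)$ receives one of four degrees of match:
Exact (1) for identical or synonym-equivalent concepts, Plugin (0.75) and
Subsume (0.5) across the subsumption hierarchy, and Dissimilar (0) when no
hierarchy chain connects them. Semantic distance is weighted: a parent with
$n$ direct subconcepts gives each child link the weight $1/n$ (a developer
can override individual edges, and overrides are never renormalized), and a
chain of links multiplies its weights:

$$d_{weight}(A,Z) = d_{weight}(A,B)\,d_{weight}(B,C)\cdots d_{weight}(Y,Z).$$

A matched pair contributes
$\mathrm{degree} \times d_{weight} / \mathrm{distance}$, where distance is
the number of hierarchy edges on the chain (0 for identical concepts, 1 for
synonyms). The aggregate applies a Jaro–Winkler-style factor adapted from
string matching to concept lists: with $m$ the summed matched degrees,
$n_C, n_P$ the list sizes, $l$ the number of non-Dissimilar pairs and
$k = 0.1$,

$$d_j = \tfrac12\left(\tfrac{m}{n_C} + \tfrac{m}{n_P}\right), \qquad
d_w = d_j + l\,k\,(1 - d_j),$$

$$\mathrm{IntoleranceScore}(C, P) =
\frac{\sum_{\text{pairs}} \mathrm{degree}_i \, d_{weight,i} /
\mathrm{distance}_i}{(n_C/n_P)\, d_w}.$$

The integer percentage divides the score by the padded pair count
$\max(n_C, n_P)$ — the maximum attainable score, since each pair term is at
most 1 — scales by 100 and truncates. The verdict is a pure function of the
pair relation multiset: RED with any Exact pair, YELLOW with only
Plugin/Subsume pairs, GREEN otherwise.

```{r}
wx <- worked_example()
res <- evaluate_product(wx$ontology, wx$consumer, wx$products$P2)
res
```

## Matching procedure and tie-breaks

Matching is greedy and sequential, not an optimal assignment: the consumer
list is walked in order, each $C_i$ is classified against every remaining
$P_j$, the pair with the maximum degree is taken and both concepts are
removed. This mirrors the stepwise procedure the scoring method defines;
a Hungarian-style optimum is a deliberate non-goal. Ties on degree are
broken by the larger contribution term, then by the lowest product index,
making the result deterministic. When list sizes differ, the shorter side
is padded with null partners (Dissimilar, term 0) to $\max(n_C, n_P)$
pairs. A property suite cross-checks the implementation against an
independently coded per-step exhaustive oracle (`oracle_match()`).

Shortest-chain ties in `path_weight()` (same edge count, different weight
products) resolve to the **maximum** weight product — the strongest
semantic link — with concept-id order as the final deterministic
tie-break.

## The direction convention

The Plugin/Subsume orientation across the hierarchy is genuinely ambiguous
in practice: prose definitions of matchmaking degrees usually make the
consumer concept a *subclass* of the product concept a Plugin, while worked
scoring examples often apply the opposite orientation. Both are
implemented behind `match_config(direction = )`:

* `"example"` (default): consumer concept strictly **above** the product
  concept → Plugin; strictly below → Subsume. The packaged worked example
  reproduces its published intermediate values under this convention.
* `"definition"`: the swap, under which a consumer subclass against its
  parent scores $0.75 \times 1/3 / 1 = 0.250$.

Sibling pairs (connected only through a common ancestor) are Subsume under
both conventions, and Exact/Dissimilar pairs are unaffected — a property
the test suite asserts on random graphs.

Two further readings were fixed after inspecting the worked arithmetic:
$l$ is the count of non-Dissimilar pairs (the Product 1 computation uses 2
with one unmatched pair; Product 2 uses 3 with all matched), and the final
score divides the pair-term sum by $(n_C/n_P)\,d_w$; when $m = 0$ the score
is defined as 0, absorbing the division singularity. When $n_P > n_C$ the
ratio $n_C/n_P < 1$ inflates the score; the formula is applied literally,
and the percentage clamp to $[0, 100]$ bounds the reported figure.

## Semantic enhancement defaults

Enhancement expands synonyms to their full closure but group and is-a
links only one hop (`hops` raises it). The default relation set is
`c("synonym", "group")`: group membership ("Ascorbate") genuinely widens
the term's equivalent forms, while is-a ancestors ("Antioxidant", "Food
Additive") are broad categories whose inclusion would flag most products;
they are opt-in. Group/is-a hops start from the entire synonym class, so
"Vitamin C" reaches the Ascorbate group through its equivalent "Ascorbic
Acid". Unresolvable terms warn and are recorded rather than failing —
packaging labels are noisy — and an entirely unresolvable list signals
`foodont_empty_list`.

The packaged worked example's consumer list is flagged `pre_enhanced`,
meaning it is already the list $C$ (size 3) and is matched as-is;
re-enhancing it would add the synonym forms of Algin and Vitamin B3 and
change $n_C$.

## Distance and pair-term conventions

Distance counts edges: 0 for the same node, 1 for synonyms or a direct
link, 2 for siblings. Identical concepts therefore have distance 0; the
pair term divides by $\max(1, \mathrm{distance})$ so an identical Exact
pair contributes exactly its degree and the per-pair cap of 1 holds.
`winkler()` clamps at 1 for $l\,k > 1$, preserving $d_w \in [d_j, 1]$.

## Rule inference

The rule engine forward-chains conjunctive SWRL-style rules
(`Body -> Head`, comma-separated unary/binary atoms, `?`-variables) to a
least fixpoint under DL-safety: variables bind only to named individuals,
every head variable must occur in a non-built-in body atom, and the only
built-ins accepted are `greaterThan`/`lessThan` on numeric arguments. Set
semantics make the fixpoint independent of rule order; a derivation cap of
$|\mathrm{individuals}|^2 \times$ (head count) guards against pathological
inputs. `expand_rule_concepts()` widens a rule's individual arguments to
every concept with a non-Dissimilar degree against them, so a product
listing "Kaolin" or "E554" still triggers the Aluminium Silicate lactose
rule. The packaged rule file covers the four risk families (lactose,
gluten, egg, fish) representatively rather than exhaustively. Rule
inference and CME scoring are reported side by side without precedence:
a fired risk rule appears in the report even when the score is low.

```{r}
ax <- allergen_example()
as.data.frame(forward_chain(ax$facts, ax$rule))
```

## Profile bands

BMI, basal metabolic rate, blood pressure and activity level are mapped to
their knowledge-base bands by `classify_bands()`. The printed ranges
overlap at endpoints (1400–1600 / 1600–1900), so a convention is required:
closed lower bound, open upper bound, final band open-ended. A boundary
value thus belongs to the band whose printed lower bound it equals
(BMI 19.0 → "normal overweight"). For blood pressure the systolic and
diastolic readings are classified separately and the more severe band is
reported. Values outside all bands return `"unclassified"`.

## Synthetic generator and what the tests show

`random_ontology()` builds a seeded layered subclass forest — acyclic by
construction — with synonym individuals and group edges attached at
configurable rates (defaults: depth 3, branching 1–3, synonym rate 0.3,
group rate 0.1, 2 roots, chosen to resemble the additive-hierarchy shape of
a real food knowledge base: shallow, moderately branched, synonym-rich).
Identical seeds give byte-identical serializations. The generator emulates
hierarchy shape only; it does not model realistic ingredient co-occurrence,
multilingual labels or annotation richness, so passing property tests
demonstrate algebraic correctness of the matching engine, not
epidemiological validity of any score on real products.

Property suites (fixed seeds) check: per-parent child weights summing to 1;
$d_j, d_w$ bounds on 1,000 random degree draws; greedy/oracle agreement on
200 random instances up to 8×8; forward-chaining monotonicity and
idempotence on 100 random fact bases against a naive substitution-
enumeration oracle; and path weights against an exhaustive simple-chain
enumeration on graphs of ≤ 40 concepts. These sizes keep the default suite
under half a minute while exercising every branch of the engine.

## Known limitations

* The OWL/XML reader supports only the four element kinds of the knowledge
  base's serialization subset — no restrictions, data properties or
  imports, and no reasoner integration.
* The fixture treats "D-Isoascorbic Acid", "Erythorbic Acid" and
  "Dehydroascorbic Acid" as one node with alternative labels rather than
  distinct chemical entities.
* The ingredient table's literal Product 2 (third ingredient "Alginic
  Acid", a synonym of Algin, hence an Exact third pair) ships as
  `worked_example(variant = "table11")`; the default variant uses Sodium
  Alginate, whose relation list the published arithmetic scores.
* Label-level fuzzy matching is out of scope: the Jaro–Winkler factor
  operates on concept lists, not strings.
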