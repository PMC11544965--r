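# The `.net` model dialect

`cvdbn` serializes fitted networks in a HUGIN-style NET dialect. HUGIN
implementations vary in minor ways, so the exact conventions used here
are spelled out; the parser is permissive on whitespace and nesting.

## Layout

```
net { }

node <name>
{
  states = ( "state 1" "state 2" ... );
}

potential ( <child> )
{
  data = ( p1 p2 ... );
}

potential ( <child> | <parent1> <parent2> ... )
{
  data = (( p11 p12 ... )
          ( p21 p22 ... )
          ...);
}
```

## Conventions

- One `node` block per variable, declaring its states in printed order;
  state labels are quoted and case-sensitive.
- One `potential` block per variable. The `data` list holds one row of
  child-state probabilities per joint parent configuration.
- Parent configurations are ordered **row-major over the declared
  parent list**: the first parent varies slowest, the last parent
  fastest, each parent stepping through its declared state order.
- Within a row, probabilities follow the child's declared state order
  and must sum to 1 (tolerance `1e-6` on parse).
- Probabilities are written with 17 significant digits, so a
  write/read round trip reproduces the model bit-for-bit.
- `%` starts a comment; inner parentheses in `data` are decorative
  (any nesting is accepted, values are read in sequence).

Decision/utility nodes, continuous nodes and other full-HUGIN features
are not supported.
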