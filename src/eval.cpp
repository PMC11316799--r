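// Compiled term-rewriting evaluator.
//
// Implements the same demand-driven semantics as the reference stepwise
// engine (leftmost-outermost, program rules in order before delta-rules,
// first match wins): variable patterns bind arguments unevaluated,
// constructor/literal patterns force to weak-head normal form, nonlinear
// patterns compare full normal forms, `if` forces only its condition and
// the chosen branch. Terms live in a per-program arena and are updated in
// place when forced (graph reduction), so shared subterms are evaluated at
// most once. Compiled programs are cached in a registry keyed by the
// program's canonical key.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

namespace {

enum Tag { T_NUM, T_BOOL, T_VAR, T_APP };

// builtin symbol ids; defined symbols follow
enum Sym {
  S_NIL, S_CONS, S_ADD, S_SUB, S_GT, S_EQ, S_IF, S_ISEMPTY,
  S_HEAD, S_TAIL, S_FIX, S_FIRST_DEFINED
};

struct Node {
  int tag;
  int a;                  // value / var slot / symbol id
  std::vector<int> kids;  // argument node ids (T_APP only)
};

struct Rule {
  int lhs;       // node id of the full lhs application (static)
  int rhs;       // node id of the rhs template (static)
  int nvars;
};

struct Program {
  std::vector<Node> arena;
  size_t n_static;
  std::unordered_map<std::string, int> symtab;
  std::vector<std::vector<Rule> > rules;  // indexed by symbol id
  int target;
};

std::unordered_map<std::string, Program> registry;

int intern_symbol(Program &p, const std::string &name) {
  std::unordered_map<std::string, int>::iterator it = p.symtab.find(name);
  if (it != p.symtab.end()) return it->second;
  int id = (int)p.symtab.size();
  p.symtab[name] = id;
  if ((int)p.rules.size() <= id) p.rules.resize(id + 1);
  return id;
}

void init_symbols(Program &p) {
  const char *names[] = {"nil", "cons", "+", "-", ">", "==", "if",
                         "is_empty", "head", "tail", "fix"};
  for (int i = 0; i < 11; ++i) intern_symbol(p, names[i]);
}

int new_node(Program &p, int tag, int a) {
  Node n; n.tag = tag; n.a = a;
  p.arena.push_back(n);
  return (int)p.arena.size() - 1;
}

// convert an R term (internal list representation) into the arena;
// vars looks up / assigns rule-local variable slots
int convert_term(Program &p, SEXP t, std::unordered_map<std::string, int> &vars) {
  if (TYPEOF(t) == INTSXP || TYPEOF(t) == REALSXP) {
    int v = Rcpp::as<Rcpp::IntegerVector>(t)[0];
    bool isna = (TYPEOF(t) == INTSXP)
      ? (INTEGER(t)[0] == NA_INTEGER)
      : ISNA(REAL(t)[0]);
    return new_node(p, T_NUM, isna ? -1 : v);
  }
  if (TYPEOF(t) == LGLSXP) {
    return new_node(p, T_BOOL, LOGICAL(t)[0] == TRUE ? 1 : 0);
  }
  if (TYPEOF(t) == STRSXP) {
    std::string nm = Rcpp::as<std::string>(t);
    std::unordered_map<std::string, int>::iterator it = vars.find(nm);
    int slot;
    if (it == vars.end()) { slot = (int)vars.size(); vars[nm] = slot; }
    else slot = it->second;
    return new_node(p, T_VAR, slot);
  }
  if (TYPEOF(t) == VECSXP) {
    Rcpp::List l(t);
    std::string op = Rcpp::as<std::string>(l[0]);
    int sym = intern_symbol(p, op);
    std::vector<int> kids;
    for (R_xlen_t i = 1; i < l.size(); ++i) {
      kids.push_back(convert_term(p, l[i], vars));
    }
    int id = new_node(p, T_APP, sym);
    p.arena[id].kids = kids;  // assign after children: new_node may realloc
    return id;
  }
  Rcpp::stop("unsupported term node");
}

struct Eval {
  Program &p;
  long fuel;
  int depth;
  bool dead;
  Eval(Program &prog, long f) : p(prog), fuel(f), depth(0), dead(false) {}

  bool spend() {
    if (--fuel < 0) { dead = true; return false; }
    return true;
  }

  bool is_defined(int sym) {
    return sym >= S_FIRST_DEFINED && !p.rules[sym].empty();
  }

  int instantiate(int tid, const std::vector<int> &binds) {
    const Node n = p.arena[tid];
    if (n.tag == T_VAR) return binds[n.a];
    if (n.tag != T_APP || n.kids.empty()) {
      if (n.tag != T_APP) return tid;       // literals are shared as-is
    }
    std::vector<int> kids(n.kids.size());
    for (size_t i = 0; i < n.kids.size(); ++i) kids[i] = instantiate(n.kids[i], binds);
    int id = new_node(p, T_APP, n.a);
    p.arena[id].kids = kids;
    return id;
  }

  // structural equality of normal forms (id equality short-circuits)
  bool equal(int a, int b) {
    if (++depth > 4000) { dead = true; --depth; return false; }
    bool r = equal_body(a, b);
    --depth;
    return r;
  }

  bool equal_body(int a, int b) {
    if (a == b) return true;
    const Node &na = p.arena[a], &nb = p.arena[b];
    if (na.tag != nb.tag || na.a != nb.a) return false;
    if (na.tag != T_APP) return true;
    if (na.kids.size() != nb.kids.size()) return false;
    for (size_t i = 0; i < na.kids.size(); ++i) {
      if (!equal(na.kids[i], nb.kids[i])) return false;
    }
    return true;
  }

  int whnf(int t);
  int nf(int t);
  int nf_body(int t);
  bool match(int pat, int parent, int argpos, std::vector<int> &binds);
  bool match_body(int pat, int parent, int argpos, std::vector<int> &binds);
  int delta(int t);
};

// force parent's argument `argpos` to whnf in place, then match
bool Eval::match(int pat, int parent, int argpos, std::vector<int> &binds) {
  if (++depth > 4000) { dead = true; --depth; return false; }
  bool r = match_body(pat, parent, argpos, binds);
  --depth;
  return r;
}

bool Eval::match_body(int pat, int parent, int argpos, std::vector<int> &binds) {
  const Node pn = p.arena[pat];
  int tid = p.arena[parent].kids[argpos];
  if (pn.tag == T_VAR) {
    if (binds[pn.a] < 0) { binds[pn.a] = tid; return true; }
    // nonlinear: compare full normal forms
    int bn = nf(binds[pn.a]); if (dead) return false;
    int tn = nf(tid); if (dead) return false;
    p.arena[parent].kids[argpos] = tn;
    binds[pn.a] = bn;
    return equal(bn, tn);
  }
  int tw = whnf(tid);
  if (dead) return false;
  p.arena[parent].kids[argpos] = tw;
  const Node &tn = p.arena[tw];
  if (pn.tag == T_NUM || pn.tag == T_BOOL) {
    return tn.tag == pn.tag && tn.a == pn.a;
  }
  // application pattern
  if (tn.tag != T_APP || tn.a != pn.a || tn.kids.size() != pn.kids.size()) return false;
  for (size_t i = 0; i < pn.kids.size(); ++i) {
    if (!match(pn.kids[i], tw, (int)i, binds)) return false;
    if (dead) return false;
  }
  return true;
}

int Eval::delta(int t) {
  Node &n0 = p.arena[t];
  int sym = n0.a;
  size_t na = n0.kids.size();
  switch (sym) {
  case S_ADD: case S_SUB: case S_GT: {
    if (na != 2) return -1;
    int x = whnf(p.arena[t].kids[0]); if (dead) return -1;
    p.arena[t].kids[0] = x;
    int y = whnf(p.arena[t].kids[1]); if (dead) return -1;
    p.arena[t].kids[1] = y;
    const Node &nx = p.arena[x], &ny = p.arena[y];
    if (nx.tag != T_NUM || ny.tag != T_NUM) return -1;
    if (sym == S_GT) {
      if (nx.a < 0 || ny.a < 0) return new_node(p, T_BOOL, 0);
      return new_node(p, T_BOOL, nx.a > ny.a ? 1 : 0);
    }
    if (nx.a < 0 || ny.a < 0) return new_node(p, T_NUM, -1);
    int r = (sym == S_ADD) ? nx.a + ny.a : nx.a - ny.a;
    return new_node(p, T_NUM, (r < 0 || r > 99) ? -1 : r);
  }
  case S_EQ: {
    if (na != 2) return -1;
    int x = nf(p.arena[t].kids[0]); if (dead) return -1;
    p.arena[t].kids[0] = x;
    int y = nf(p.arena[t].kids[1]); if (dead) return -1;
    p.arena[t].kids[1] = y;
    return new_node(p, T_BOOL, equal(x, y) ? 1 : 0);
  }
  case S_IF: {
    if (na != 3) return -1;
    int c = whnf(p.arena[t].kids[0]); if (dead) return -1;
    p.arena[t].kids[0] = c;
    const Node &nc = p.arena[c];
    if (nc.tag != T_BOOL) return -1;
    return nc.a ? p.arena[t].kids[1] : p.arena[t].kids[2];
  }
  case S_ISEMPTY: case S_HEAD: case S_TAIL: {
    if (na != 1) return -1;
    int x = whnf(p.arena[t].kids[0]); if (dead) return -1;
    p.arena[t].kids[0] = x;
    const Node &nx = p.arena[x];
    if (nx.tag != T_APP) return -1;
    if (nx.a == S_NIL) {
      if (sym == S_ISEMPTY) return new_node(p, T_BOOL, 1);
      if (sym == S_HEAD) return new_node(p, T_NUM, -1);   // head [] = nan
      return x;                                           // tail [] = []
    }
    if (nx.a != S_CONS || nx.kids.size() != 2) return -1;
    if (sym == S_ISEMPTY) return new_node(p, T_BOOL, 0);
    return (sym == S_HEAD) ? nx.kids[0] : nx.kids[1];
  }
  case S_FIX: {
    // fixpoint iteration over normal forms
    if (na != 2) return -1;
    int f = p.arena[t].kids[1];
    if (p.arena[f].tag != T_APP || !p.arena[f].kids.empty()) return -1;
    int fsym = p.arena[f].a;
    int x = nf(p.arena[t].kids[0]); if (dead) return -1;
    int fx_app = new_node(p, T_APP, fsym);
    p.arena[fx_app].kids.push_back(x);
    int fx = nf(fx_app); if (dead) return -1;
    if (equal(fx, x)) return x;
    int nxt = new_node(p, T_APP, S_FIX);
    p.arena[nxt].kids.push_back(fx);
    p.arena[nxt].kids.push_back(f);
    return nxt;
  }
  default:
    return -1;
  }
}

int Eval::whnf(int t) {
  if (++depth > 8000) { dead = true; --depth; return t; }
  for (;;) {
    if (dead || !spend()) break;
    const Node &n = p.arena[t];
    if (n.tag != T_APP) {
      if (n.tag == T_VAR) dead = true;
      break;
    }
    int sym = n.a;
    if (sym == S_NIL || sym == S_CONS) break;
    if (is_defined(sym)) {
      bool fired = false;
      size_t nk = n.kids.size();
      const std::vector<Rule> &rs = p.rules[sym];
      for (size_t ri = 0; ri < rs.size(); ++ri) {
        const Rule &r = rs[ri];
        if (p.arena[r.lhs].kids.size() != nk) continue;
        std::vector<int> binds((size_t)r.nvars, -1);
        bool ok = true;
        for (size_t i = 0; i < nk; ++i) {
          if (!match(p.arena[r.lhs].kids[i], t, (int)i, binds)) { ok = false; break; }
          if (dead) { --depth; return t; }
        }
        if (ok) {
          t = instantiate(r.rhs, binds);
          fired = true;
          break;
        }
      }
      if (fired) continue;
      dead = true;   // defined symbol, no matching rule: stuck
      break;
    }
    int r = delta(t);
    if (dead) break;
    if (r < 0) { dead = true; break; }
    t = r;
  }
  --depth;
  return t;
}

int Eval::nf(int t) {
  if (++depth > 4000) { dead = true; --depth; return t; }
  int r = nf_body(t);
  --depth;
  return r;
}

int Eval::nf_body(int t) {
  t = whnf(t);
  if (dead) return t;
  Node &n = p.arena[t];
  if (n.tag != T_APP) {
    if (n.tag == T_VAR) dead = true;
    return t;
  }
  if (n.a == S_NIL) return t;
  if (n.a == S_CONS && n.kids.size() == 2) {
    int x = nf(p.arena[t].kids[0]); if (dead) return t;
    p.arena[t].kids[0] = x;
    int xs = nf(p.arena[t].kids[1]); if (dead) return t;
    p.arena[t].kids[1] = xs;
    return t;
  }
  dead = true;   // non-constructor normal form: stuck
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".mpl_eval_cpp")]]
SEXP mpl_eval_cpp(std::string key, SEXP rules, std::string target,
                  Rcpp::IntegerVector input, double fuel) {
  std::unordered_map<std::string, Program>::iterator it = registry.find(key);
  if (it == registry.end()) {
    if (registry.size() > 8000) registry.clear();
    Program prog;
    init_symbols(prog);
    Rcpp::List rl(rules);
    for (R_xlen_t i = 0; i < rl.size(); ++i) {
      Rcpp::List r(rl[i]);
      std::unordered_map<std::string, int> vars;
      Rule rule;
      rule.lhs = convert_term(prog, r["lhs"], vars);
      rule.rhs = convert_term(prog, r["rhs"], vars);
      rule.nvars = (int)vars.size();
      const Node &lhs = prog.arena[rule.lhs];
      if (lhs.tag != T_APP) Rcpp::stop("rule lhs must be an application");
      prog.rules[lhs.a].push_back(rule);
    }
    prog.target = intern_symbol(prog, target);
    prog.n_static = prog.arena.size();
    it = registry.insert(std::make_pair(key, prog)).first;
  }
  Program &prog = it->second;
  prog.arena.resize(prog.n_static);   // drop scratch from previous calls

  // build the input list term
  int t = new_node(prog, T_APP, S_NIL);
  for (R_xlen_t i = input.size() - 1; i >= 0; --i) {
    int h = new_node(prog, T_NUM,
                     input[i] == NA_INTEGER ? -1 : input[i]);
    int c = new_node(prog, T_APP, S_CONS);
    prog.arena[c].kids.push_back(h);
    prog.arena[c].kids.push_back(t);
    t = c;
  }
  int call = new_node(prog, T_APP, prog.target);
  prog.arena[call].kids.push_back(t);

  Eval ev(prog, (long)fuel);
  int v = ev.nf(call);

  // decode the cons spine (before releasing scratch storage)
  bool ok = !ev.dead;
  std::vector<int> out;
  int cur = v;
  while (ok) {
    const Node &n = prog.arena[cur];
    if (n.tag != T_APP) { ok = false; break; }
    if (n.a == S_NIL) break;
    if (n.a != S_CONS || n.kids.size() != 2) { ok = false; break; }
    const Node &h = prog.arena[n.kids[0]];
    if (h.tag != T_NUM) { ok = false; break; }
    out.push_back(h.a);
    cur = n.kids[1];
  }

  // drop the scratch nodes and return their storage: thousands of cached
  // programs would otherwise each retain their peak evaluation arena
  prog.arena.resize(prog.n_static);
  prog.arena.shrink_to_fit();

  if (!ok) return R_NilValue;
  Rcpp::IntegerVector res((int)out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    res[(int)i] = out[i] < 0 ? NA_INTEGER : out[i];
  }
  return res;
}

// [[Rcpp::export(name = ".mpl_eval_registry_size")]]
int mpl_eval_registry_size() { return (int)registry.size(); }
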