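#!/usr/bin/env python
"""Independent oracle for the steady-state PET (physiologically equivalent
temperature) computation.

Implements the three-node (core / skin / clothing) steady-state human energy
balance ("MEMI") and the PET equivalence search as an independent coding,
using numpy + scipy (fsolve for the coupled node system, brentq for the PET
root).  The R package under ../R implements the same published formulation
with its own solver stack (damped Newton + uniroot); this script exists so
the two routes can be cross-checked.

Usage:
    python tools/pet_oracle.py grid  > tests/testthat/pet-oracle-grid.csv
    python tools/pet_oracle.py point TA VP TMRT V [CLO WORK]
"""
import sys

import numpy as np
from scipy.optimize import brentq, fsolve

SBC = 5.67e-8       # Stefan-Boltzmann [W m-2 K-4]
E_SKIN = 0.99       # skin emissivity
E_CLO = 0.95        # clothing emissivity
H_VAP = 2.42e6      # latent heat of vaporisation [J kg-1]
C_BLOOD = 3640.0    # blood specific heat [J kg-1 K-1]
C_AIR = 1010.0      # air specific heat [J kg-1 K-1]
LEWIS = 1.67        # Lewis ratio [K hPa-1]
I_M = 0.38          # Woodcock moisture permeability index
P_ATM = 1013.25     # [hPa]
TC_SET = 36.6       # core set point [degC]
TSK_SET = 34.0      # skin set point [degC]


def esat(t):
    """Magnus saturation vapour pressure [hPa], t in degC."""
    return 6.112 * np.exp(17.62 * t / (243.12 + t))


def body_surface(weight, height):
    return 0.202 * weight ** 0.425 * height ** 0.725


def basal_metabolism(sex, age, height, weight):
    if sex == "female":
        return 3.19 * weight ** 0.75 * (
            1.0 + 0.004 * (30.0 - age)
            + 0.018 * (height * 100.0 / weight ** (1.0 / 3.0) - 42.1))
    return 3.45 * weight ** 0.75 * (
        1.0 + 0.004 * (30.0 - age)
        + 0.010 * (height * 100.0 / weight ** (1.0 / 3.0) - 43.4))


def blood_flow(t_cr, t_sk):
    sig_core = max(t_cr - TC_SET, 0.0)
    sig_skin = max(TSK_SET - t_sk, 0.0)
    m_blood = (6.3 + 75.0 * sig_core) / (1.0 + 0.5 * sig_skin)
    return min(m_blood, 90.0)


def alpha_mix(m_blood):
    return 0.0417737 + 0.7451833 / (m_blood + 0.585417)


def sweat_rate(t_body):
    t_body_set = 0.1 * TSK_SET + 0.9 * TC_SET
    return min(304.94e-3 * max(t_body - t_body_set, 0.0), 500.0)


def balance(t_arr, ta, vpa, tr, v, clo, work, sex, age, height, weight):
    """Vector of the three nodal energy balances [W m-2]."""
    t_cr, t_sk, t_clo = t_arr
    a_du = body_surface(weight, height)
    he = (work + basal_metabolism(sex, age, height, weight)) / a_du
    h = he  # mechanical efficiency 0

    # respiration
    t_exp = 0.47 * ta + 21.0
    d_vent = he * 1.44e-6
    c_res = C_AIR * (ta - t_exp) * d_vent
    q_res = 0.623 * H_VAP / P_ATM * (vpa - esat(t_exp)) * d_vent
    ere = c_res + q_res

    # convection coefficient, seated subject
    hc = 2.67 + 6.5 * v ** 0.67

    # clothing geometry
    fcl = 1.0 + 0.31 * clo
    f_a_cl = (173.51 * clo - 2.36 - 100.76 * clo ** 2 + 19.28 * clo ** 3) / 100.0
    f_a_cl = min(f_a_cl, 1.0)
    a_clo = a_du * (f_a_cl + fcl - 1.0)
    f_eff = 0.696
    r_cl = clo / 6.45
    if clo >= 2.0:
        y = 1.0
    elif clo > 0.6:
        y = (height - 0.2) / height
    elif clo > 0.3:
        y = 0.5
    else:
        y = 0.1
    r2 = a_du * (fcl - 1.0 + f_a_cl) / (6.28 * height * y)
    r1 = f_a_cl * a_du / (6.28 * height * y)
    htcl = 6.28 * height * y * (r2 - r1) / (r_cl * np.log(r2 / r1) * a_clo)

    # physiology
    m_blood = blood_flow(t_cr, t_sk)
    alpha = alpha_mix(m_blood)
    t_body = alpha * t_sk + (1.0 - alpha) * t_cr
    esw = H_VAP / 1000.0 * sweat_rate(t_body) / 3600.0

    # evaporation
    e_sk = esat(t_sk)
    fecl = 1.0 / (1.0 + 0.92 * hc * r_cl)
    e_max = hc * LEWIS * fecl * (e_sk - vpa)
    if e_max <= 0.0:
        w = 1.0
        esw = 0.0
    else:
        w = min(esw / e_max, 1.0)
        esw = min(esw, e_max)
    r_ecl = (1.0 / (fcl * hc) + r_cl) / (LEWIS * I_M)
    ediff = (1.0 - w) * (e_sk - vpa) / r_ecl
    evap = -(esw + ediff)

    # radiation and convection, bare and clothed fractions
    tr_k4 = (tr + 273.15) ** 4
    r_bare = f_eff * (1.0 - f_a_cl) * E_SKIN * SBC * (tr_k4 - (t_sk + 273.15) ** 4)
    r_clo_ = f_eff * (a_clo / a_du) * E_CLO * SBC * (tr_k4 - (t_clo + 273.15) ** 4)
    c_bare = hc * (ta - t_sk) * (1.0 - f_a_cl)
    c_clo = hc * (ta - t_clo) * a_clo / a_du

    cond = 5.28 + C_BLOOD * m_blood / 3600.0
    b_core = h + ere - cond * (t_cr - t_sk)
    b_skin = (r_bare + c_bare + evap + cond * (t_cr - t_sk)
              - htcl * (t_sk - t_clo))
    b_clo = r_clo_ + c_clo + htcl * (t_sk - t_clo)
    return np.array([b_core, b_skin, b_clo])


def solve_state(ta, vpa, tr, v, clo, work, sex="male", age=35,
                height=1.75, weight=75.0):
    guess = np.array([36.7, 34.0, 0.5 * (ta + tr)])
    sol = fsolve(balance, guess,
                 args=(ta, vpa, tr, v, clo, work, sex, age, height, weight),
                 full_output=False, xtol=1e-10)
    return sol


def pet(ta, vpa, tr, v, clo=0.9, work=80.0, sex="male", age=35,
        height=1.75, weight=75.0):
    state = solve_state(ta, vpa, tr, v, clo, work, sex, age, height, weight)

    def ref_balance(tx):
        return balance(state, tx, 12.0, tx, 0.1, 0.9, 80.0,
                       sex, age, height, weight).sum()

    return brentq(ref_balance, -60.0, 90.0, xtol=1e-4)


def main():
    mode = sys.argv[1] if len(sys.argv) > 1 else "grid"
    if mode == "point":
        ta, vp, tr, v = (float(x) for x in sys.argv[2:6])
        clo = float(sys.argv[6]) if len(sys.argv) > 6 else 0.9
        work = float(sys.argv[7]) if len(sys.argv) > 7 else 80.0
        st = solve_state(ta, vp, tr, v, clo, work)
        print("t_core=%.6f t_skin=%.6f t_clo=%.6f pet=%.6f"
              % (st[0], st[1], st[2], pet(ta, vp, tr, v, clo, work)))
        return
    rng = np.random.RandomState(20220314)
    n = 50
    ta = rng.uniform(15.0, 40.0, n)
    tr = rng.uniform(15.0, 60.0, n)
    vp = rng.uniform(5.0, 25.0, n)
    v = rng.uniform(0.1, 2.0, n)
    print("ta,vp,tmrt,v,pet")
    for i in range(n):
        print("%.4f,%.4f,%.4f,%.4f,%.6f"
              % (ta[i], vp[i], tr[i], v[i], pet(ta[i], vp[i], tr[i], v[i])))


if __name__ == "__main__":
    main()
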