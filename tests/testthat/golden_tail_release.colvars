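# colvars bias protocol: tail_release

colvar {
    name cv_wall_dmin_tails_outer
    distanceInv {
        exponent 100
        group1 { roles=H3-A+H2A-A segment=tail atoms=CA }
        group2 { roles=DNA region=outer_gyre_3p atoms=P }
    }
}
harmonicWalls {
    name wall_dmin_tails_outer
    colvars { cv_wall_dmin_tails_outer }
    forceConstant 10
    lowerWalls 12
}

colvar {
    name cv_wall_coord_tails_outer
    coordNum {
        cutoff 4
        expNumer 6
        expDenom 12
        group1 { roles=H3-A+H2A-A segment=tail atoms=CA }
        group2 { roles=DNA region=outer_gyre_3p atoms=P }
    }
}
harmonicWalls {
    name wall_coord_tails_outer
    colvars { cv_wall_coord_tails_outer }
    forceConstant 10
    upperWalls 0
}
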